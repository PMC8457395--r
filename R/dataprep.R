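## Dataset construction and cleaning: structure filters, farthest-neighbour
## diversity sampling, empirical shielding-to-shift scaling, IQR outlier
## removal of paired computed/experimental shifts, and reproducible splits.

#' Filter structures for dataset inclusion
#'
#' Keeps molecules that are neutral (total formal charge zero), lighter
#' than 500 g/mol (strictly), restricted to the supported element set
#' C, H, O, N, F, Cl, P, S and, optionally, with all stereocentres defined.
#'
#' @param entries list of entries as returned by [readStructures()], or a
#'   list of [Molecule-class] objects.
#' @param require_stereo_defined reject molecules with any undefined
#'   stereocentre annotation.
#' @return A list with elements \code{kept} (the surviving subset, same
#'   form as the input), \code{reasons} (named integer counts per rejection
#'   reason) and \code{rejected} (data.frame of id/reason).
#' @export
filterStructures <- function(entries, require_stereo_defined = FALSE) {
  getMol <- function(e) if (is(e, "Molecule")) e else e$molecule
  reasons <- c(charge = 0L, mw = 0L, element = 0L, stereo = 0L)
  keep <- logical(length(entries))
  rej <- list()
  for (k in seq_along(entries)) {
    mol <- getMol(entries[[k]])
    why <- NULL
    if (sum(formalCharges(mol)) != 0L) why <- "charge"
    else if (length(setdiff(unique(atomElements(mol)), .SUPPORTED_ELEMENTS)))
      why <- "element"
    else if (molWeight(mol) >= 500) why <- "mw"
    else if (require_stereo_defined && length(stereoDefined(mol)) &&
             !all(stereoDefined(mol))) why <- "stereo"
    if (is.null(why)) keep[k] <- TRUE
    else {
      reasons[[why]] <- reasons[[why]] + 1L
      rej[[length(rej) + 1L]] <- data.frame(id = molId(mol), reason = why)
    }
  }
  list(kept = entries[keep], reasons = reasons,
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(id = character(), reason = character()))
}

#' Binary fingerprints for a set of molecules
#'
#' Atom-pair descriptors (ChemmineR) computed from the bond graph and
#' folded into a fixed-width bit vector by modular hashing; used as the
#' similarity basis for diversity sampling.  Any logical matrix with one
#' row per molecule can substitute.
#'
#' @param entries list of [readStructures()] entries or Molecule objects;
#'   connectivity (bonds) must be present.
#' @param nbits fingerprint width.
#' @return Logical matrix, one row per molecule.
#' @export
moleculeFingerprints <- function(entries, nbits = 1024L) {
  getE <- function(e) if (is(e, "Molecule")) list(molecule = e) else e
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  con <- file(tmp, "w")
  for (e in entries) {
    e <- getE(e)
    cf <- if (length(e$conformers)) e$conformers[[1]] else
      Conformer(molId(e$molecule),
                matrix(seq_len(3 * length(atomElements(e$molecule))),
                       ncol = 3) * 0.7, NA_real_, "user")
    .writeMolV2000(con, e$molecule, cf)
  }
  close(con)
  sdfset <- ChemmineR::read.SDFset(tmp)
  apset <- suppressWarnings(ChemmineR::sdf2ap(sdfset))
  descs <- ChemmineR::ap(apset)
  fp <- matrix(FALSE, length(descs), nbits)
  for (k in seq_along(descs)) {
    d <- descs[[k]]
    ## single-heavy-atom molecules have no atom pairs; leave the row empty
    if (length(d) && !(length(d) == 1L && d[1] == 0))
      fp[k, (as.numeric(d) %% nbits) + 1L] <- TRUE
  }
  rownames(fp) <- vapply(entries, function(e) molId(getE(e)$molecule), "")
  fp
}

#' Greedy farthest-neighbour (max-min) diversity sampling
#'
#' Starts from a seeded pick and repeatedly adds the item whose minimum
#' Jaccard distance (1 - Tanimoto) to the selected set is largest.
#' Deterministic given the seed; ties resolve to the lowest index.
#'
#' @param fps logical matrix of bit fingerprints, one row per item.
#' @param k number of items to select (k <= nrow(fps)).
#' @param seed RNG seed controlling the initial pick.
#' @return Integer vector of k selected row indices (selection order).
#' @export
farthestNeighborSample <- function(fps, k, seed = 1L) {
  fps <- as.matrix(fps)
  n <- nrow(fps)
  if (k > n) stop("k (", k, ") exceeds the number of items (", n, ")")
  if (k < 1L) stop("k must be >= 1")
  set.seed(seed)
  start <- sample.int(n)[1L]
  sel <- integer(k)
  sel[1L] <- start
  rs <- rowSums(fps)
  ## minimum Jaccard distance from every item to the selected set
  jaccDist <- function(i) {
    inter <- as.vector(fps %*% fps[i, ])
    uni <- rs + rs[i] - inter
    d <- 1 - ifelse(uni > 0, inter / uni, 1)
    d
  }
  minD <- jaccDist(start)
  if (k > 1L) for (m in 2:k) {
    minD[sel[seq_len(m - 1L)]] <- -Inf
    pick <- which(minD == max(minD))[1L]   # ties: lowest index
    sel[m] <- pick
    minD <- pmin(minD, jaccDist(pick))
  }
  sel
}

#' Empirical shielding-to-shift scaling relation
#'
#' Maps an isotropic shielding sigma (ppm) to a chemical shift via
#' \eqn{\delta = a - s\,\sigma}.
#'
#' @param intercept a, ppm.
#' @param slope s, dimensionless, positive.
#' @param nucleus \code{"H1"} or \code{"C13"}.
#' @return A list of class \code{"scalingRelation"}.
#' @export
scalingRelation <- function(intercept, slope, nucleus = c("C13", "H1")) {
  nucleus <- match.arg(nucleus)
  stopifnot(is.finite(intercept), is.finite(slope), slope > 0)
  structure(list(intercept = intercept, slope = slope, nucleus = nucleus),
            class = "scalingRelation")
}

#' Default scaling relations
#'
#' The empirical linear maps used to turn GIAO isotropic shieldings into
#' chemical shifts: delta = 181.40 - 0.97 sigma for 13C and
#' delta = 29.30 - 0.91 sigma for 1H.
#'
#' @param nucleus \code{"C13"} or \code{"H1"}.
#' @return A [scalingRelation()].
#' @export
#' @examples
#' scaleShielding(0, defaultScaling("C13"))    # 181.40
#' scaleShielding(100, defaultScaling("C13"))  # 84.40
defaultScaling <- function(nucleus = c("C13", "H1")) {
  nucleus <- match.arg(nucleus)
  switch(nucleus,
         C13 = scalingRelation(181.40, 0.97, "C13"),
         H1 = scalingRelation(29.30, 0.91, "H1"))
}

#' Apply a scaling relation
#'
#' @param sigma isotropic shielding(s), ppm.
#' @param rel a [scalingRelation()].
#' @return Chemical shift(s) \code{rel$intercept - rel$slope * sigma}, ppm.
#' @export
scaleShielding <- function(sigma, rel) {
  stopifnot(inherits(rel, "scalingRelation"))
  rel$intercept - rel$slope * sigma
}

#' IQR cleaning of paired computed/experimental shifts
#'
#' Pools the differences (computed - experimental) across the dataset for a
#' single nucleus, computes quartiles by linear interpolation of order
#' statistics, and keeps a pair iff its difference lies within
#' [Q1 - 1.5 IQR, Q3 + 1.5 IQR] (inclusive on both bounds, so degenerate
#' all-equal data are fully retained).
#'
#' @param computed,experimental shift-record data.frames matched by
#'   (molecule_id, atom, nucleus); a single nucleus per call.
#' @param perMolecule compute quartiles per molecule instead of pooled
#'   (non-default variant; the pooled rule is the reference behaviour).
#' @return A list of class \code{"cleaningReport"}: per-record differences,
#'   Q1/Q3/IQR, bounds, kept flags, removed fraction, and MAE/RMSE of the
#'   computed-vs-experimental agreement before and after cleaning.
#' @export
cleanByIQR <- function(computed, experimental, perMolecule = FALSE) {
  for (df in list(computed, experimental))
    if (length(unique(df$nucleus)) != 1L)
      stop("cleanByIQR handles a single nucleus per call")
  if (unique(computed$nucleus) != unique(experimental$nucleus))
    stop("computed and experimental tables disagree on the nucleus")
  key <- function(df) paste(df$molecule_id, df$atom, df$nucleus, sep = "|")
  m <- match(key(computed), key(experimental))
  if (anyNA(m))
    stop("unmatched computed record(s): ",
         paste(utils::head(key(computed)[is.na(m)], 3), collapse = "; "))
  exp2 <- experimental[m, , drop = FALSE]
  diffs <- computed$shift - exp2$shift
  n <- length(diffs)
  if (n < 4L) stop("need at least 4 pairs for quartile estimation")
  qfun <- function(d) {
    q <- stats::quantile(d, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    c(q1 = q[1], q3 = q[2], iqr = iqr,
      lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
  }
  if (perMolecule) {
    kept <- logical(n)
    st <- qfun(diffs)  # pooled summary still reported
    for (id in unique(computed$molecule_id)) {
      ix <- which(computed$molecule_id == id)
      s <- if (length(ix) >= 4L) qfun(diffs[ix]) else st
      kept[ix] <- diffs[ix] >= s[["lower"]] & diffs[ix] <= s[["upper"]]
    }
  } else {
    st <- qfun(diffs)
    kept <- diffs >= st[["lower"]] & diffs <= st[["upper"]]
  }
  err <- function(d) c(mae = mean(abs(d)), rmse = sqrt(mean(d^2)))
  structure(list(
    differences = diffs, q1 = st[["q1"]], q3 = st[["q3"]], iqr = st[["iqr"]],
    lower = st[["lower"]], upper = st[["upper"]], kept = kept,
    removedFraction = mean(!kept),
    before = err(diffs), after = err(diffs[kept]),
    quartileEstimator = "linear interpolation (type 7)",
    pooled = !perMolecule), class = "cleaningReport")
}

#' @export
print.cleaningReport <- function(x, ...) {
  cat(sprintf(
    "IQR cleaning (%s): n = %d, Q1 = %.3f, Q3 = %.3f, IQR = %.3f\n",
    if (x$pooled) "pooled" else "per-molecule",
    length(x$differences), x$q1, x$q3, x$iqr))
  cat(sprintf("  bounds [%.3f, %.3f]; removed %.2f%%\n",
              x$lower, x$upper, 100 * x$removedFraction))
  cat(sprintf("  RMSE %.3f -> %.3f ppm; MAE %.3f -> %.3f ppm\n",
              x$before[["rmse"]], x$after[["rmse"]],
              x$before[["mae"]], x$after[["mae"]]))
  invisible(x)
}

#' Reproducible molecule-level train/validation/test split
#'
#' @param ids molecule identifiers (no conformer of one molecule can land
#'   in two splits because splitting happens at the id level).
#' @param n_val,n_test validation/test set sizes.
#' @param seed RNG seed.
#' @return List with character vectors \code{train}, \code{val},
#'   \code{test}: disjoint, exhaustive, deterministic given the seed.
#' @export
splitDataset <- function(ids, n_val = 500L, n_test = 500L, seed = 1L) {
  ids <- unique(as.character(ids))
  n <- length(ids)
  if (n_val + n_test >= n)
    stop("need more ids (", n, ") than n_val + n_test (", n_val + n_test, ")")
  set.seed(seed)
  perm <- sample(ids)
  list(train = perm[seq_len(n - n_val - n_test)],
       val = perm[(n - n_val - n_test + 1L):(n - n_test)],
       test = perm[(n - n_test + 1L):n])
}
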