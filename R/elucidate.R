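## Structure assignment by shift matching: sorted-list MAE comparison of
## candidate structures against experimental spectra, global (cumulative)
## spectrum-to-candidate assignment, and detection/repair of per-atom
## misassignments by optimal reordering of experimental values.
##
## For one-to-one matching that minimises the mean absolute difference,
## pairing both lists in sorted order is optimal (a classic rearrangement
## argument); the property suite verifies this against exhaustive search.

.shiftVec <- function(x, nucleus = NULL) {
  if (is(x, "EnsemblePrediction")) {
    if (!is.null(nucleus) && nucleusOf(x) != nucleus)
      stop("prediction nucleus ", nucleusOf(x), " does not match requested ",
           nucleus)
    return(finalShifts(x))
  }
  if (is.data.frame(x)) {
    if (!is.null(nucleus)) {
      if (!all(x$nucleus == nucleus))
        stop("shift table contains nuclei other than ", nucleus)
    }
    return(stats::setNames(x$shift, x$atom))
  }
  stats::setNames(as.numeric(x), names(x))
}

#' Sorted-shift matching of a prediction against an experiment
#'
#' Sorts both lists ascending and pairs them positionally; the MAE over the
#' pairs scores the candidate.  With \code{allowTruncate} unequal lengths
#' are permitted: the longer (sorted) list contributes the contiguous
#' window that minimises the MAE, and the dropped extremes are recorded.
#' Silent truncation can flip rankings, so the strict mode is the default.
#'
#' @param pred,exp numeric shift vectors (ppm); also accepts
#'   [EnsemblePrediction-class] or shift-record data.frames.
#' @param id candidate identifier carried into the result.
#' @param allowTruncate permit unequal lengths (with a warning).
#' @return A list of class \code{"candidateResult"}: \code{candidate_id},
#'   \code{pairs} (sorted pred/exp values), \code{mae}, \code{errors}
#'   (per-pair absolute errors), \code{dropped} (values left unmatched).
#' @export
#' @examples
#' matchSorted(c(10, 20), c(19, 12))$mae   # pairs (10,12),(20,19): 1.5
matchSorted <- function(pred, exp, id = "candidate", allowTruncate = FALSE) {
  p <- sort(as.numeric(.shiftVec(pred)))
  e <- sort(as.numeric(.shiftVec(exp)))
  if (!length(p) || !length(e)) stop("cannot match empty shift lists")
  dropped <- numeric()
  if (length(p) != length(e)) {
    if (!allowTruncate)
      stop("shift lists differ in length (", length(p), " vs ", length(e),
           "); use allowTruncate to pair the sorted overlap")
    warning("pairing sorted overlap; ", abs(length(p) - length(e)),
            " value(s) dropped from the longer list")
    k <- min(length(p), length(e))
    long <- if (length(p) > length(e)) p else e
    short <- if (length(p) > length(e)) e else p
    offs <- 0:(length(long) - k)
    maes <- vapply(offs, function(o) mean(abs(long[o + seq_len(k)] - short)),
                   numeric(1))
    o <- offs[which.min(maes)]
    dropped <- long[-(o + seq_len(k))]
    if (length(p) > length(e)) p <- long[o + seq_len(k)] else
      e <- long[o + seq_len(k)]
  }
  err <- abs(p - e)
  structure(list(candidate_id = id,
                 pairs = data.frame(pred = p, exp = e),
                 mae = mean(err), errors = err, dropped = dropped),
            class = "candidateResult")
}

#' @export
print.candidateResult <- function(x, ...) {
  cat(sprintf("candidate '%s': %d matched pairs, MAE %.3f ppm%s\n",
              x$candidate_id, nrow(x$pairs), x$mae,
              if (length(x$dropped)) sprintf(" (%d dropped)",
                                             length(x$dropped)) else ""))
  invisible(x)
}

## Exact assignment by bitmask dynamic programming over candidate subsets.
## cost: n x n matrix (rows = spectra, cols = candidates).  Returns the
## column assigned to each row, minimising the total cost.
.assignmentDP <- function(cost) {
  n <- nrow(cost)
  if (n > 20L) stop("exact assignment supported up to 20 spectra")
  full <- bitwShiftL(1L, n) - 1L
  best <- rep(Inf, full + 1L); best[1L] <- 0
  choice <- integer(full + 1L)
  for (mask in 0:(full - 1L)) {
    if (!is.finite(best[mask + 1L])) next
    r <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0L) + 1L  # next row
    for (c in seq_len(n)) {
      bit <- bitwShiftL(1L, c - 1L)
      if (bitwAnd(mask, bit) > 0L) next
      nm <- bitwOr(mask, bit)
      v <- best[mask + 1L] + cost[r, c]
      if (v < best[nm + 1L]) { best[nm + 1L] <- v; choice[nm + 1L] <- c }
    }
  }
  assign <- integer(n); mask <- full
  for (r in n:1) {
    c <- choice[mask + 1L]
    assign[r] <- c
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, c - 1L)))
  }
  assign
}

#' Rank candidate structures against experimental spectra
#'
#' In \code{"rank"} mode every candidate is scored against one experimental
#' spectrum by [matchSorted()] and returned in ascending-MAE order (ties
#' keep input order and are flagged).  In \code{"global"} mode \code{exp}
#' is a list of spectra, one per candidate, and the spectrum-to-candidate
#' bijection minimising the cumulative MAE is found exactly -- the variant
#' that rescues assignments where a per-spectrum argmin misassigns a pair.
#'
#' @param candidates named list of predictions ([EnsemblePrediction-class],
#'   shift-record data.frame, or numeric vector).
#' @param exp one spectrum (\code{"rank"}) or a named list of spectra
#'   (\code{"global"}).
#' @param nucleus consistency check for typed inputs.
#' @param mode \code{"rank"} or \code{"global"}.
#' @param allowTruncate passed to [matchSorted()].
#' @return \code{"rank"}: list of \code{candidateResult}s, ascending MAE,
#'   with attribute \code{"ties"}.  \code{"global"}: data.frame
#'   (spectrum, candidate, mae) plus attribute \code{"totalMAE"}.
#' @export
rankCandidates <- function(candidates, exp, nucleus = "C13",
                           mode = c("rank", "global"),
                           allowTruncate = FALSE) {
  mode <- match.arg(mode)
  if (is.null(names(candidates)))
    names(candidates) <- sprintf("candidate%d", seq_along(candidates))
  vecs <- lapply(candidates, .shiftVec, nucleus = nucleus)
  if (mode == "rank") {
    e <- .shiftVec(exp, nucleus)
    res <- Map(function(v, id) matchSorted(v, e, id, allowTruncate),
               vecs, names(candidates))
    maes <- vapply(res, `[[`, numeric(1), "mae")
    ord <- order(maes)  # stable: ties keep input order
    out <- unname(res[ord])
    attr(out, "ties") <- any(duplicated(signif(maes, 12)))
    return(out)
  }
  if (!is.list(exp) || length(exp) != length(candidates))
    stop("global mode needs one spectrum per candidate")
  if (is.null(names(exp))) names(exp) <- sprintf("spectrum%d", seq_along(exp))
  es <- lapply(exp, .shiftVec, nucleus = nucleus)
  cost <- matrix(0, length(es), length(vecs))
  for (s in seq_along(es)) for (c in seq_along(vecs))
    cost[s, c] <- matchSorted(vecs[[c]], es[[s]], allowTruncate = allowTruncate)$mae
  assign <- .assignmentDP(cost)
  out <- data.frame(spectrum = names(es),
                    candidate = names(vecs)[assign],
                    mae = cost[cbind(seq_along(es), assign)])
  attr(out, "totalMAE") <- sum(out$mae)
  out
}

#' Optimal reassignment of experimental shifts to atoms
#'
#' Finds the permutation of the experimental values over the atoms that
#' minimises the MAE against the atom-wise predictions.  Because the cost
#' is an absolute difference, sorting both sides yields the exact optimum;
#' with \code{classes} supplied (e.g. CH-multiplicity classes) values are
#' only permuted within a class, the constrained variant.
#'
#' @param pred,exp atom-indexed shifts (named numeric vectors or
#'   data.frames with \code{atom}, \code{shift}); equal counts required.
#' @param threshold structures whose as-assigned MAE exceeds this (strictly)
#'   are flagged as candidate misassignments (ppm).
#' @param classes optional factor over atoms restricting swaps.
#' @return A list of class \code{"reassignmentResult"}: \code{permutation}
#'   (for each atom, the atom whose experimental value it receives),
#'   \code{reordered} (the permuted experimental values), \code{maeBefore},
#'   \code{maeAfter} (always <= before), \code{flagged}.
#' @export
#' @examples
#' # swapped alpha/beta enoate-like carbons come back corrected
#' optimalReassignment(c(a1 = 128, a2 = 150), c(a1 = 150, a2 = 128))$maeAfter
optimalReassignment <- function(pred, exp, threshold = 3.5, classes = NULL) {
  p <- .shiftVec(pred); e <- .shiftVec(exp)
  if (length(p) != length(e))
    stop("prediction and experiment must cover the same atom count (",
         length(p), " vs ", length(e), ")")
  if (!is.null(names(p)) && !is.null(names(e))) {
    if (!setequal(names(p), names(e)))
      stop("prediction and experiment cover different atoms")
    e <- e[names(p)]
  }
  n <- length(p)
  atoms <- names(p) %||% as.character(seq_len(n))
  if (is.null(classes)) classes <- factor(rep(1L, n))
  classes <- as.factor(classes)
  perm <- integer(n)
  ## within each class: k-th smallest prediction gets k-th smallest value
  for (cl in levels(classes)) {
    ix <- which(classes == cl)
    rankP <- rank(p[ix], ties.method = "first")
    srcSorted <- ix[order(e[ix])]
    perm[ix] <- srcSorted[rankP]
  }
  reordered <- e[perm]
  maeBefore <- mean(abs(p - e))
  maeAfter <- mean(abs(p - reordered))
  structure(list(
    atoms = atoms,
    permutation = stats::setNames(atoms[perm], atoms),
    reordered = stats::setNames(as.numeric(reordered), atoms),
    maeBefore = maeBefore, maeAfter = maeAfter,
    flagged = maeBefore > threshold, threshold = threshold),
    class = "reassignmentResult")
}

#' @export
print.reassignmentResult <- function(x, ...) {
  moved <- sum(x$permutation != x$atoms)
  cat(sprintf(
    "reassignment over %d atoms: MAE %.3f -> %.3f ppm, %d value(s) moved%s\n",
    length(x$atoms), x$maeBefore, x$maeAfter, moved,
    if (x$flagged) sprintf(" [flagged: before-MAE > %.1f ppm]",
                           x$threshold) else ""))
  invisible(x)
}

#' Flag candidate misassignments
#'
#' @param results list of \code{candidateResult}s.
#' @param threshold ppm; strictly-greater comparison.
#' @return The flagged subset (possibly empty list).
#' @export
flagOutliers <- function(results, threshold = 3.5) {
  if (inherits(results, "candidateResult")) results <- list(results)
  Filter(function(r) r$mae > threshold, results)
}
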