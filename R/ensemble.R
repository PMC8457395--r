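## Conformer ensembles: generation (OpenBabel confab + MMFF94 energies),
## Boltzmann weighting, and ensemble-averaged shift prediction.

## Gas constant, kcal/(mol K)
.R_KCAL <- 1.98720425864083e-3

#' Boltzmann weights from relative energies
#'
#' \eqn{w_i = \exp(-E_i/RT) / \sum_j \exp(-E_j/RT)}, computed stably by
#' subtracting the minimum energy first.  Weights are invariant to adding
#' any constant to all energies and approach uniformity as T grows.
#'
#' @param rel_energies numeric vector, kcal/mol.
#' @param T temperature, Kelvin (default 298.15).
#' @return Numeric weights summing to one.
#' @export
#' @examples
#' boltzmannWeights(c(0, 0))          # 0.5 0.5
#' boltzmannWeights(c(0, 0.41))       # ratio exp(-0.41/(R*298.15))
boltzmannWeights <- function(rel_energies, T = 298.15) {
  if (!length(rel_energies)) stop("empty energy list")
  if (!all(is.finite(rel_energies))) stop("energies must be finite")
  if (T <= 0) stop("temperature must be positive")
  e <- rel_energies - min(rel_energies)
  w <- exp(-e / (.R_KCAL * T))
  w / sum(w)
}

## Kabsch-aligned RMSD of two coordinate sets (rows paired)
.alignedRMSD <- function(A, B) {
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  s <- svd(crossprod(B, A))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((A %*% R - B)^2)))
}

#' Generate conformers with MMFF94 relative energies
#'
#' Embeds the molecule in 3D and enumerates conformers with OpenBabel's
#' systematic torsion search (confab), then evaluates MMFF94 energies and
#' deduplicates by heavy-atom RMSD after optimal superposition (keeping the
#' lower-energy member of a close pair).  Deterministic for a given
#' molecule: the torsion search is systematic.
#'
#' @param mol a [Molecule-class] (bonds required) or a SMILES string.
#' @param max_confs maximum number of conformers returned.
#' @param seed retained for interface stability; the search is systematic
#'   and the seed only breaks ties in degenerate energy sorts.
#' @param rmsdCutoff heavy-atom RMSD (Angstrom) below which two conformers
#'   are considered duplicates.
#' @param conf optional starting [Conformer-class]; when absent the
#'   geometry is embedded from scratch.
#' @return List of [Conformer-class] objects with MMFF94 relative energies
#'   (kcal/mol, minimum at 0), sorted by energy.
#' @export
generateConformers <- function(mol, max_confs = 200L, seed = 1L,
                               rmsdCutoff = 0.5, conf = NULL) {
  if (max_confs < 1L) stop("max_confs must be >= 1")
  if (!.haveOpenBabel())
    stop("conformer generation requires OpenBabel (obabel) on the PATH")
  tmpin <- tempfile(fileext = if (is.character(mol)) ".smi" else ".sdf")
  tmp3d <- tempfile(fileext = ".sdf")
  tmpcf <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tmpin, tmp3d, tmpcf)))
  if (is.character(mol)) {
    writeLines(mol, tmpin)
    molName <- mol
    args3d <- c("-ismi", shQuote(tmpin), "-osdf", "-O", shQuote(tmp3d),
                "-h", "--gen3d")
  } else {
    stopifnot(is(mol, "Molecule"))
    if (!nrow(bondTable(mol)))
      stop("molecule '", molId(mol), "' has no connectivity; cannot embed")
    molName <- molId(mol)
    if (is.null(conf)) {
      writeStructuresSDF(mol, list(Conformer(molId(mol),
        matrix(stats::runif(3 * length(atomElements(mol))),
               ncol = 3), NA_real_, "user")), tmpin)
      args3d <- c(shQuote(tmpin), "-osdf", "-O", shQuote(tmp3d), "--gen3d")
    } else {
      writeStructuresSDF(mol, list(conf), tmpin)
      args3d <- c(shQuote(tmpin), "-osdf", "-O", shQuote(tmp3d))
    }
  }
  st <- suppressWarnings(system2("obabel", args3d,
                                 stdout = FALSE, stderr = FALSE))
  if (st != 0 || !file.exists(tmp3d) || file.size(tmp3d) == 0)
    stop("3D embedding failed for molecule '", molName, "'")
  st <- suppressWarnings(system2("obabel",
    c(shQuote(tmp3d), "-O", shQuote(tmpcf), "--confab",
      "--conf", format(max_confs * 5L), "--rcutoff", format(rmsdCutoff)),
    stdout = FALSE, stderr = FALSE))
  if (st != 0 || !file.exists(tmpcf) || file.size(tmpcf) == 0)
    stop("conformer search failed for molecule '", molName, "'")
  entries <- readStructures(tmpcf, "sdf")
  if (!length(entries)) stop("conformer search produced no structures")
  ## MMFF94 energies, one per record, in file order
  en <- suppressWarnings(system2("obenergy",
    c("-ff", "MMFF94", shQuote(tmpcf)), stdout = TRUE, stderr = FALSE))
  ev <- as.numeric(sub(".*=\\s*([-0-9.eE+]+).*", "\\1",
                       grep("TOTAL ENERGY", en, value = TRUE)))
  if (length(ev) != length(entries))
    stop("energy evaluation failed for molecule '", molName, "' (",
         length(ev), " energies for ", length(entries), " conformers)")
  rel <- ev - min(ev)
  ord <- order(rel)
  heavy <- which(atomElements(entries[[1]]$molecule) != "H")
  kept <- list(); keptIdx <- integer()
  for (i in ord) {
    xyz <- coords(entries[[i]]$conformers[[1]])
    dup <- any(vapply(kept, function(prev)
      .alignedRMSD(xyz[heavy, , drop = FALSE], prev) < rmsdCutoff,
      logical(1)))
    if (!dup) {
      kept[[length(kept) + 1L]] <- xyz[heavy, , drop = FALSE]
      keptIdx <- c(keptIdx, i)
      if (length(keptIdx) >= max_confs) break
    }
  }
  lapply(keptIdx, function(i)
    Conformer(if (is.character(mol)) molName else molId(mol),
              coords(entries[[i]]$conformers[[1]]), rel[i], "mmff"))
}

#' Boltzmann-weighted ensemble prediction
#'
#' Predicts per-conformer shifts for the masked atoms and averages them
#' with Boltzmann weights computed from the conformers' relative energies.
#' Per-conformer values are retained for inspection; the final shift is a
#' convex combination, so it always lies between the per-conformer
#' extremes.
#'
#' @param model a trained [ShiftModel-class].
#' @param mol the [Molecule-class].
#' @param conformers list of [Conformer-class] objects with relative
#'   energies (required when more than one conformer is supplied).
#' @param T temperature in Kelvin for the weights.
#' @param rbf [rbfParams()] used for graph construction.
#' @return An [EnsemblePrediction-class].
#' @export
predictEnsemble <- function(model, mol, conformers, T = 298.15,
                            rbf = rbfParams()) {
  if (!length(conformers)) stop("no conformers supplied")
  for (cf in conformers)
    if (molId(cf) != molId(mol))
      stop("conformer of '", molId(cf), "' does not belong to molecule '",
           molId(mol), "'")
  nC <- length(conformers)
  energies <- vapply(conformers, relEnergy, numeric(1))
  if (nC == 1L) {
    w <- 1
  } else {
    if (anyNA(energies))
      stop("relative energies are required to weight ", nC, " conformers")
    w <- boltzmannWeights(energies, T)
  }
  graphs <- lapply(conformers, buildGraph, mol = mol, params = rbf,
                   nucleus = nucleusOf(model))
  pred <- predictShifts(model, graphs)
  atomIdx <- sort(unique(pred$atom))
  perConf <- matrix(NA_real_, nC, length(atomIdx))
  for (g in seq_len(nC)) {
    rows <- pred[pred$graph == g, ]
    perConf[g, ] <- rows$shift[match(atomIdx, rows$atom)]
  }
  new("EnsemblePrediction", moleculeId = molId(mol), perConformer = perConf,
      atomIndex = as.integer(atomIdx), weights = as.numeric(w),
      finalShifts = as.numeric(drop(crossprod(perConf, w))),
      temperature = T, nucleus = nucleusOf(model))
}
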