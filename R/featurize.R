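#' Radial-basis expansion parameters
#'
#' Distances are encoded on a grid of Gaussian basis functions with centres
#' at \code{k * mu}, k = 0 .. n_basis - 1, and width parameter \code{delta}:
#' component k of the expansion of a distance d is
#' \deqn{e_k(d) = \exp(-(d - k\mu)^2 / \delta).}
#' The defaults (256 basis functions, mu = 0.1 Angstrom, delta = 0.04
#' Angstrom^2, 5 Angstrom cutoff) are the values used throughout the package.
#'
#' @param n_basis number of basis functions.
#' @param delta Gaussian width parameter (Angstrom^2).
#' @param mu centre spacing (Angstrom).
#' @param cutoff neighbour cutoff (Angstrom, strict).
#' @return A validated list of class \code{"rbfParams"}.
#' @export
#' @examples
#' p <- rbfParams()
#' rbfExpand(1.09, p)[11:12]   # centres at 1.0 and 1.1 Angstrom
rbfParams <- function(n_basis = 256L, delta = 0.04, mu = 0.1, cutoff = 5.0) {
  stopifnot(n_basis >= 1L, delta > 0, mu > 0, cutoff > 0)
  structure(list(n_basis = as.integer(n_basis), delta = delta, mu = mu,
                 cutoff = cutoff), class = "rbfParams")
}

#' Expand distances over the radial basis
#'
#' @param d numeric vector of distances (Angstrom), all strictly positive.
#' @param params an [rbfParams()] object.
#' @return A length(d) x n_basis matrix; every entry lies in (0, 1], and
#'   component k (0-based) of row m is maximal when \code{d[m] == k * mu}.
#' @export
rbfExpand <- function(d, params = rbfParams()) {
  if (any(d <= 0))
    stop("rbfExpand: distances must be strictly positive (self-pairs must not reach the expansion)")
  centers <- (seq_len(params$n_basis) - 1L) * params$mu
  exp(-(outer(d, centers, "-"))^2 / params$delta)
}

#' Build the environment graph of a conformer
#'
#' Links every ordered atom pair strictly closer than the cutoff by a
#' directed edge carrying the interatomic distance and its RBF expansion.
#' The target mask marks the atoms whose element matches the requested
#' nucleus (H for H1, C for C13).
#'
#' @param conf a [Conformer-class].
#' @param mol the parent [Molecule-class].
#' @param params an [rbfParams()] object.
#' @param nucleus \code{"H1"} or \code{"C13"}.
#' @return An [EnvironmentGraph-class].
#' @export
#' @examples
#' fx <- makeFixture("methane")
#' g <- buildGraph(fx$conformers[[1]], fx$molecule, nucleus = "C13")
#' g
buildGraph <- function(conf, mol, params = rbfParams(), nucleus = c("C13", "H1")) {
  nucleus <- match.arg(nucleus)
  xyz <- coords(conf)
  n <- nrow(xyz)
  if (n != length(atomElements(mol)))
    stop("atom-count mismatch between conformer (", n, ") and molecule '",
         molId(mol), "' (", length(atomElements(mol)), ")")
  if (n > 1L) {
    dm <- as.matrix(stats::dist(xyz))
    sel <- which(dm > 0 & dm < params$cutoff & row(dm) != col(dm), arr.ind = TRUE)
    ## stable order: by receiver, then sender
    sel <- sel[order(sel[, 1L], sel[, 2L]), , drop = FALSE]
    edges <- unname(cbind(sel[, 1L], sel[, 2L]))
    dvec <- dm[sel]
  } else {
    edges <- matrix(integer(), 0L, 2L)
    dvec <- numeric()
  }
  storage.mode(edges) <- "integer"
  feats <- if (length(dvec)) rbfExpand(dvec, params) else
    matrix(numeric(), 0L, params$n_basis)
  targetElem <- c(H1 = "H", C13 = "C")[[nucleus]]
  new("EnvironmentGraph", elements = atomElements(mol), edges = edges,
      distances = dvec, features = feats,
      targetMask = atomElements(mol) == targetElem,
      nucleus = nucleus, rbf = unclass(params))
}

#' Dump a graph to debug JSON
#'
#' Writes nodes, edges and distances (not the full RBF matrix) for
#' inspection and test fixtures.
#'
#' @param graph an [EnvironmentGraph-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
graphToJSON <- function(graph, path) {
  obj <- list(
    elements = atomElements(graph),
    nucleus = nucleusOf(graph),
    target_atoms = which(targetMask(graph)),
    edges = edgeTable(graph),
    rbf = graph@rbf
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
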