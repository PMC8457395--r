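#' @import methods
NULL

## Elements the models know about.  Order fixes the embedding-table rows, so
## it must never be permuted once a model has been trained.
.SUPPORTED_ELEMENTS <- c("C", "H", "O", "N", "F", "Cl", "P", "S")

## Monoisotopic-free standard atomic weights (g/mol), used for MW filtering.
## A few common extras are included so that out-of-scope molecules can still
## be weighed (and then rejected by the element filter).
.ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
  B = 10.81, Si = 28.085, Se = 78.971, Na = 22.990, K = 39.098,
  Li = 6.94, Mg = 24.305, Ca = 40.078, Zn = 65.38, Fe = 55.845
)

#' Molecule: elements, bonds and per-atom annotations
#'
#' Atom indices are 1-based everywhere in memory; the on-disk CSV schema uses
#' 0-based \code{atom_index} and is converted at the I/O boundary.
#'
#' @slot id single molecule identifier.
#' @slot elements character vector of element symbols, one per atom.
#' @slot bonds integer matrix with columns \code{from}, \code{to},
#'   \code{order}; zero rows when connectivity is unknown (e.g. XYZ input).
#' @slot formalCharges integer vector, one per atom.
#' @slot stereoDefined logical vector, one entry per stereocentre
#'   (\code{TRUE} = configuration specified); length zero when the molecule
#'   has no stereocentres or none were annotated.
#'
#' @exportClass Molecule
setClass("Molecule", representation(
  id = "character",
  elements = "character",
  bonds = "matrix",
  formalCharges = "integer",
  stereoDefined = "logical"
))

setValidity("Molecule", function(object) {
  n <- length(object@elements)
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (n < 1L) msg <- c(msg, "molecule must contain at least one atom")
  if (length(object@formalCharges) != n)
    msg <- c(msg, "'formalCharges' length must equal atom count")
  b <- object@bonds
  if (ncol(b) != 3L) msg <- c(msg, "'bonds' must have 3 columns (from, to, order)")
  else if (nrow(b) > 0L) {
    if (any(b[, 1:2] < 1L) || any(b[, 1:2] > n))
      msg <- c(msg, "bond atom indices out of range")
    if (any(b[, 1L] == b[, 2L])) msg <- c(msg, "bond connects an atom to itself")
  }
  if (length(msg)) msg else TRUE
})

#' Conformer: one 3D geometry of a molecule
#'
#' @slot moleculeId id of the parent [Molecule-class].
#' @slot coords numeric N x 3 matrix of Cartesian coordinates in Angstrom.
#' @slot relEnergy relative energy in kcal/mol (NA when unknown).
#' @slot source one of \code{"mmff"}, \code{"dft"}, \code{"user"}.
#'
#' @exportClass Conformer
setClass("Conformer", representation(
  moleculeId = "character",
  coords = "matrix",
  relEnergy = "numeric",
  source = "character"
))

setValidity("Conformer", function(object) {
  msg <- character()
  xyz <- object@coords
  if (ncol(xyz) != 3L) msg <- c(msg, "'coords' must be an N x 3 matrix")
  if (!all(is.finite(xyz))) msg <- c(msg, "'coords' must be finite")
  if (nrow(xyz) > 1L) {
    d <- stats::dist(xyz)
    if (any(d < 1e-8)) msg <- c(msg, "two atoms share identical coordinates")
  }
  if (length(object@source) != 1L || !object@source %in% c("mmff", "dft", "user"))
    msg <- c(msg, "'source' must be one of 'mmff', 'dft', 'user'")
  if (length(object@relEnergy) != 1L)
    msg <- c(msg, "'relEnergy' must be a single number (possibly NA)")
  if (length(msg)) msg else TRUE
})

#' Environment graph: the network's view of one conformer
#'
#' Nodes are atoms; a directed edge links every ordered atom pair closer than
#' the cutoff (strictly), carrying the distance and its radial-basis
#' expansion.  The target mask marks atoms of the element matching the
#' nucleus of interest.
#'
#' @slot elements element symbol per node.
#' @slot edges integer E x 2 matrix of (receiver i, sender j) pairs.
#' @slot distances numeric vector of edge lengths (Angstrom).
#' @slot features numeric E x n_basis matrix of RBF-expanded distances.
#' @slot targetMask logical per node.
#' @slot nucleus \code{"H1"} or \code{"C13"}.
#' @slot rbf the [rbfParams()] list used to build the graph.
#'
#' @exportClass EnvironmentGraph
setClass("EnvironmentGraph", representation(
  elements = "character",
  edges = "matrix",
  distances = "numeric",
  features = "matrix",
  targetMask = "logical",
  nucleus = "character",
  rbf = "list"
))

setValidity("EnvironmentGraph", function(object) {
  msg <- character()
  n <- length(object@elements)
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "'edges' must have two columns")
  if (nrow(e) != length(object@distances) || nrow(e) != nrow(object@features))
    msg <- c(msg, "edges, distances and features disagree in length")
  if (length(object@targetMask) != n)
    msg <- c(msg, "'targetMask' length must equal node count")
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > n)) msg <- c(msg, "edge indices out of range")
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-edges are not allowed")
    cutoff <- object@rbf$cutoff
    if (!is.null(cutoff) && any(object@distances >= cutoff))
      msg <- c(msg, "edge beyond cutoff")
    if (any(object@distances <= 0)) msg <- c(msg, "non-positive edge distance")
    ## symmetry: (i,j) present iff (j,i) present
    key <- paste(e[, 1L], e[, 2L])
    rev <- paste(e[, 2L], e[, 1L])
    if (!setequal(key, rev)) msg <- c(msg, "edge set not closed under reversal")
  }
  if (length(msg)) msg else TRUE
})

#' Trained (or freshly initialised) message-passing shift model
#'
#' Parameters are stored as a named list of numeric matrices/vectors; the
#' parallel \code{groups} vector assigns every tensor to one of the
#' functional groups \code{embedding}, \code{edge_update}, \code{message},
#' \code{node_update}, \code{readout} used by the transfer-learning freeze
#' schemes.
#'
#' @slot config model configuration list, see [modelConfig()].
#' @slot params named list of parameter tensors.
#' @slot groups named character vector: tensor name -> group label.
#' @slot nucleus \code{"H1"} or \code{"C13"}.
#' @slot elements embedding-row order of element symbols.
#' @slot targetCenter,targetScale affine output mapping (ppm); set on first
#'   training and never refit by retraining stages.
#' @slot lineage list of provenance entries (parent checkpoint id, freeze
#'   scheme, data fingerprint) appended by each (re)training.
#'
#' @exportClass ShiftModel
setClass("ShiftModel", representation(
  config = "list",
  params = "list",
  groups = "character",
  nucleus = "character",
  elements = "character",
  targetCenter = "numeric",
  targetScale = "numeric",
  lineage = "list"
))

setValidity("ShiftModel", function(object) {
  msg <- character()
  if (!setequal(names(object@params), names(object@groups)))
    msg <- c(msg, "every parameter tensor must carry exactly one group label")
  bad <- setdiff(unique(object@groups),
                 c("embedding", "edge_update", "message", "node_update", "readout"))
  if (length(bad)) msg <- c(msg, paste("unknown group label:", paste(bad, collapse = ", ")))
  if (!object@nucleus %in% c("H1", "C13")) msg <- c(msg, "nucleus must be 'H1' or 'C13'")
  if (length(msg)) msg else TRUE
})

#' Boltzmann-weighted ensemble prediction
#'
#' @slot moleculeId parent molecule id.
#' @slot perConformer numeric C x A matrix: one row per conformer, one
#'   column per target atom (ppm).
#' @slot atomIndex integer vector of target atom indices (1-based).
#' @slot weights Boltzmann weight per conformer (sums to one).
#' @slot finalShifts weighted-average shift per target atom (ppm).
#' @slot temperature Kelvin used for the weights.
#' @slot nucleus \code{"H1"} or \code{"C13"}.
#'
#' @exportClass EnsemblePrediction
setClass("EnsemblePrediction", representation(
  moleculeId = "character",
  perConformer = "matrix",
  atomIndex = "integer",
  weights = "numeric",
  finalShifts = "numeric",
  temperature = "numeric",
  nucleus = "character"
))

setValidity("EnsemblePrediction", function(object) {
  msg <- character()
  if (length(object@weights) != nrow(object@perConformer))
    msg <- c(msg, "one weight per conformer required")
  if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-12)
    msg <- c(msg, "weights must be non-negative and sum to 1 within 1e-12")
  if (length(object@finalShifts) != ncol(object@perConformer))
    msg <- c(msg, "one final shift per target atom required")
  if (length(object@atomIndex) != length(object@finalShifts))
    msg <- c(msg, "'atomIndex' must align with final shifts")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "Molecule", function(object) {
  comp <- table(object@elements)
  cat(sprintf("Molecule '%s': %d atoms (%s), %d bonds, MW %.2f\n",
              object@id, length(object@elements),
              paste(names(comp), as.integer(comp), sep = "", collapse = " "),
              nrow(object@bonds), molWeight(object)))
})

setMethod("show", "Conformer", function(object) {
  cat(sprintf("Conformer of '%s': %d atoms, source %s, rel. energy %s kcal/mol\n",
              object@moleculeId, nrow(object@coords), object@source,
              ifelse(is.na(object@relEnergy), "NA",
                     sprintf("%.3f", object@relEnergy))))
})

setMethod("show", "EnvironmentGraph", function(object) {
  cat(sprintf(
    "EnvironmentGraph: %d nodes, %d directed edges (< %.1f Angstrom), %d RBF, nucleus %s (%d targets)\n",
    length(object@elements), nrow(object@edges), object@rbf$cutoff,
    ncol(object@features), object@nucleus, sum(object@targetMask)))
})

setMethod("show", "ShiftModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("ShiftModel (%s): %d tensors, %d parameters, %d update blocks, feature dim %d\n",
              object@nucleus, length(object@params), np,
              object@config$n_update_blocks, object@config$feature_dim))
  if (length(object@lineage))
    cat(sprintf("  lineage: %d training stage(s), last scheme '%s'\n",
                length(object@lineage),
                object@lineage[[length(object@lineage)]]$scheme))
})

setMethod("show", "EnsemblePrediction", function(object) {
  cat(sprintf("EnsemblePrediction '%s' (%s): %d conformers x %d atoms at %.2f K\n",
              object@moleculeId, object@nucleus, nrow(object@perConformer),
              ncol(object@perConformer), object@temperature))
})
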