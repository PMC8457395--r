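#' @name accessors
#' @title Accessors for ShiftGNN objects
#'
#' @description Slot accessors; user code should use these instead of
#' \code{@}-access.
#'
#' @param object a ShiftGNN S4 object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("molId", function(object) standardGeneric("molId"))
#' @rdname accessors
#' @export
setGeneric("atomElements", function(object) standardGeneric("atomElements"))
#' @rdname accessors
#' @export
setGeneric("bondTable", function(object) standardGeneric("bondTable"))
#' @rdname accessors
#' @export
setGeneric("formalCharges", function(object) standardGeneric("formalCharges"))
#' @rdname accessors
#' @export
setGeneric("stereoDefined", function(object) standardGeneric("stereoDefined"))
#' @rdname accessors
#' @export
setGeneric("molWeight", function(object) standardGeneric("molWeight"))
#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("relEnergy", function(object) standardGeneric("relEnergy"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("targetMask", function(object) standardGeneric("targetMask"))
#' @rdname accessors
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))
#' @rdname accessors
#' @export
setGeneric("paramGroups", function(object) standardGeneric("paramGroups"))
#' @rdname accessors
#' @export
setGeneric("nucleusOf", function(object) standardGeneric("nucleusOf"))
#' @rdname accessors
#' @export
setGeneric("finalShifts", function(object) standardGeneric("finalShifts"))
#' @rdname accessors
#' @export
setGeneric("conformerWeights", function(object) standardGeneric("conformerWeights"))
#' @rdname accessors
#' @export
setGeneric("perConformerShifts", function(object) standardGeneric("perConformerShifts"))

setMethod("molId", "Molecule", function(object) object@id)
setMethod("molId", "Conformer", function(object) object@moleculeId)
setMethod("molId", "EnsemblePrediction", function(object) object@moleculeId)
setMethod("atomElements", "Molecule", function(object) object@elements)
setMethod("atomElements", "EnvironmentGraph", function(object) object@elements)
setMethod("bondTable", "Molecule", function(object) object@bonds)
setMethod("formalCharges", "Molecule", function(object) object@formalCharges)
setMethod("stereoDefined", "Molecule", function(object) object@stereoDefined)
setMethod("molWeight", "Molecule", function(object) {
  w <- .ATOMIC_WEIGHTS[object@elements]
  if (anyNA(w))
    stop("no atomic weight tabulated for element(s): ",
         paste(unique(object@elements[is.na(w)]), collapse = ", "))
  sum(w)
})
setMethod("coords", "Conformer", function(object) object@coords)
setMethod("relEnergy", "Conformer", function(object) object@relEnergy)
setMethod("edgeTable", "EnvironmentGraph", function(object) {
  data.frame(i = object@edges[, 1L], j = object@edges[, 2L],
             distance = object@distances)
})
setMethod("targetMask", "EnvironmentGraph", function(object) object@targetMask)
setMethod("modelParams", "ShiftModel", function(object) object@params)
setMethod("paramGroups", "ShiftModel", function(object) object@groups)
setMethod("nucleusOf", "ShiftModel", function(object) object@nucleus)
setMethod("nucleusOf", "EnvironmentGraph", function(object) object@nucleus)
setMethod("nucleusOf", "EnsemblePrediction", function(object) object@nucleus)
setMethod("finalShifts", "EnsemblePrediction", function(object) {
  stats::setNames(object@finalShifts, object@atomIndex)
})
setMethod("conformerWeights", "EnsemblePrediction", function(object) object@weights)
setMethod("perConformerShifts", "EnsemblePrediction", function(object) object@perConformer)

#' Construct a Molecule
#'
#' @param id molecule identifier.
#' @param elements character vector of element symbols.
#' @param bonds optional matrix/data.frame with columns from, to, order
#'   (1-based atom indices).
#' @param formalCharges integer vector per atom (default all zero).
#' @param stereoDefined logical vector, one per stereocentre (default none).
#' @return A [Molecule-class] object.
#' @export
#' @examples
#' Molecule("ethanol-heavy", c("C", "C", "O"),
#'          bonds = cbind(c(1, 2), c(2, 3), c(1, 1)))
Molecule <- function(id, elements, bonds = NULL, formalCharges = NULL,
                     stereoDefined = logical()) {
  n <- length(elements)
  if (is.null(bonds)) bonds <- matrix(integer(), 0L, 3L)
  bonds <- as.matrix(bonds)
  if (nrow(bonds)) storage.mode(bonds) <- "integer"
  colnames(bonds) <- c("from", "to", "order")
  if (is.null(formalCharges)) formalCharges <- integer(n)
  new("Molecule", id = as.character(id), elements = as.character(elements),
      bonds = bonds, formalCharges = as.integer(formalCharges),
      stereoDefined = as.logical(stereoDefined))
}

#' Construct a Conformer
#'
#' @param moleculeId parent molecule id.
#' @param coords numeric N x 3 matrix, Angstrom.
#' @param relEnergy relative energy in kcal/mol, NA when unknown.
#' @param source geometry provenance: "mmff", "dft" or "user".
#' @return A [Conformer-class] object.
#' @export
Conformer <- function(moleculeId, coords, relEnergy = NA_real_, source = "user") {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  storage.mode(coords) <- "double"
  new("Conformer", moleculeId = as.character(moleculeId), coords = coords,
      relEnergy = as.numeric(relEnergy), source = source)
}

#' Supported element set
#'
#' The elements the dataset filters admit and the models embed.
#' @return Character vector of element symbols.
#' @export
supportedElements <- function() .SUPPORTED_ELEMENTS
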