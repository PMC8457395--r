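## Transfer learning = freeze schemes over parameter groups.
##
## Stage 1 (computed -> experimental labels, same geometries): retrain the
## readout only, everything else frozen.  Stage 2 (experimental labels,
## force-field geometries): retrain the edge-update blocks only, everything
## else frozen.  Freezing operates at tensor granularity via group labels.

.SCHEMES <- list(
  none = character(),
  readout_only = c("embedding", "edge_update", "message", "node_update"),
  edge_update_only = c("embedding", "message", "node_update", "readout")
)

#' Freeze scheme definition
#'
#' @param name \code{"none"}, \code{"readout_only"} or
#'   \code{"edge_update_only"}.
#' @return A list with the scheme name and the set of frozen group labels.
#' @export
#' @examples
#' freezeScheme("readout_only")$frozen_groups
freezeScheme <- function(name = c("none", "readout_only", "edge_update_only")) {
  name <- match.arg(name)
  list(name = name, frozen_groups = .SCHEMES[[name]])
}

#' Build a freeze mask from a scheme
#'
#' @param model a [ShiftModel-class].
#' @param scheme a [freezeScheme()] (or its name).
#' @return Named logical vector over parameter tensors, TRUE = frozen, with
#'   attributes \code{scheme} and \code{frozenFraction} (fraction of scalar
#'   parameters frozen).
#' @export
#' @examples
#' m <- initModel(modelConfig(feature_dim = 8, n_basis = 8,
#'                            readout_layer_widths = c(8, 4, 1)))
#' mask <- makeFreezeMask(m, "readout_only")
#' attr(mask, "frozenFraction")
makeFreezeMask <- function(model, scheme) {
  if (is.character(scheme)) scheme <- freezeScheme(scheme)
  groups <- paramGroups(model)
  bad <- setdiff(scheme$frozen_groups, unique(groups))
  if (length(bad))
    stop("unknown parameter group(s) in scheme: ", paste(bad, collapse = ", "))
  mask <- stats::setNames(groups %in% scheme$frozen_groups, names(groups))
  attr(mask, "scheme") <- scheme$name
  attr(mask, "frozenFraction") <- .frozenFraction(model, mask)
  mask
}

#' Retrain a model under a freeze scheme
#'
#' Delegates to [trainModel()] with the scheme's mask; the optimizer state
#' is restarted (no momentum carry-over between stages) and the default
#' learning rate is one tenth of the initial-training default, the usual
#' fine-tuning convention.  Lineage metadata (parent fingerprint, scheme,
#' data fingerprint) is appended to the returned model.
#'
#' @inheritParams trainModel
#' @param scheme a [freezeScheme()] or its name.
#' @return As [trainModel()].
#' @export
retrainModel <- function(model, data, scheme, valData = NULL, epochs = 30L,
                         batchSize = 16L, lr = 1e-4, patience = 10L,
                         seed = 1L, verbose = FALSE) {
  if (!length(model@lineage))
    warning("retraining a model with no training lineage; ",
            "did you mean trainModel()?")
  mask <- makeFreezeMask(model, scheme)
  trainModel(model, data, valData = valData, epochs = epochs,
             batchSize = batchSize, lr = lr, patience = patience,
             freezeMask = mask, seed = seed, verbose = verbose)
}
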