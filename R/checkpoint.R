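## Checkpoints: a versioned single-file archive of config, parameters,
## group labels, target scaling and lineage.  Save/load round-trips are
## bitwise stable for the parameter tensors.

.CHECKPOINT_FORMAT <- 1L

#' Save a model checkpoint
#'
#' @param model a [ShiftModel-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "ShiftModel"))
  obj <- list(
    format = .CHECKPOINT_FORMAT,
    package_version = as.character(utils::packageVersion("ShiftGNN")),
    config = model@config,
    params = model@params,
    groups = model@groups,
    nucleus = model@nucleus,
    elements = model@elements,
    targetCenter = model@targetCenter,
    targetScale = model@targetScale,
    lineage = model@lineage
  )
  saveRDS(obj, path, version = 2)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [saveCheckpoint()].
#' @return A [ShiftModel-class].
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, .CHECKPOINT_FORMAT))
    stop("unsupported checkpoint format: ", obj$format)
  new("ShiftModel", config = obj$config, params = obj$params,
      groups = obj$groups, nucleus = obj$nucleus, elements = obj$elements,
      targetCenter = obj$targetCenter, targetScale = obj$targetScale,
      lineage = obj$lineage)
}
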