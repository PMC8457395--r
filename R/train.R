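## Training: Adam on MAE (or MSE) loss over standardised targets, whole
## molecules per batch, best-validation parameters kept, learning rate
## halved when the validation loss plateaus.

#' Attach per-atom labels to an environment graph
#'
#' @param graph an [EnvironmentGraph-class].
#' @param shifts either a numeric vector with one ppm value per masked atom
#'   (in increasing atom order), or a shift-record data.frame (as returned
#'   by [parseShiftTable()] / [oracleShifts()]) from which the masked atoms'
#'   values are pulled by atom index.
#' @return A list with elements \code{graph} and \code{y}, the unit of the
#'   training-set lists consumed by [trainModel()] and [evaluateModel()].
#' @export
labeledGraph <- function(graph, shifts) {
  idx <- which(targetMask(graph))
  if (is.data.frame(shifts)) {
    m <- match(idx, shifts$atom)
    if (anyNA(m))
      stop("shift table lacks values for masked atom(s): ",
           paste(idx[is.na(m)], collapse = ", "))
    y <- shifts$shift[m]
  } else {
    y <- as.numeric(shifts)
  }
  if (length(y) != length(idx) || !all(is.finite(y)))
    stop("labels must be finite and cover exactly the ", length(idx),
         " masked atoms")
  list(graph = graph, y = y)
}

## Cheap deterministic fingerprint of any R object (hex string).
.fingerprint <- function(obj) {
  raw <- serialize(obj, NULL, version = 2)
  v <- as.numeric(raw)
  sprintf("%08x", as.integer(sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647))
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adamStep <- function(params, grads, state, lr, frozen,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (n in names(params)) {
    if (isTRUE(frozen[[n]])) next
    g <- grads[[n]]
    state$m[[n]] <- beta1 * state$m[[n]] + (1 - beta1) * g
    state$v[[n]] <- beta2 * state$v[[n]] + (1 - beta2) * g * g
    step <- lr * (state$m[[n]] / c1) / (sqrt(state$v[[n]] / c2) + eps)
    params[[n]] <- params[[n]] - array(step, dim(params[[n]]) %||% length(step))
  }
  list(params = params, state = state)
}

.checkData <- function(model, data, what = "training") {
  if (!length(data)) stop("empty ", what, " set")
  for (d in data) {
    if (!inherits(d$graph, "EnvironmentGraph") || is.null(d$y))
      stop(what, " data must be a list of labeledGraph() entries")
    if (nucleusOf(d$graph) != nucleusOf(model))
      stop("graph nucleus does not match model nucleus")
    if (ncol(d$graph@features) != model@config$n_basis)
      stop("graph RBF dimension does not match the model's n_basis")
    if (length(d$y) != sum(targetMask(d$graph)))
      stop("label count does not match masked atom count")
  }
  invisible(TRUE)
}

.lossGrad <- function(resid, loss) {
  n <- length(resid)
  switch(loss, mae = sign(resid) / n, mse = 2 * resid / n)
}

.batchLoss <- function(resid, loss) {
  switch(loss, mae = mean(abs(resid)), mse = mean(resid^2))
}

#' Train a shift model
#'
#' Mini-batch Adam over whole molecules; targets are standardised internally
#' by the model's affine output scaling (set from the labels on the first
#' training and left untouched afterwards).  The parameters achieving the
#' lowest validation loss are returned (earliest epoch wins ties); frozen
#' tensors are never modified, bitwise.
#'
#' @param model a [ShiftModel-class].
#' @param data training set: list of [labeledGraph()] entries.
#' @param valData validation set in the same form (must be disjoint from
#'   \code{data}); when NULL the training loss drives model selection.
#' @param epochs maximum number of epochs.
#' @param batchSize molecules per gradient step.
#' @param lr initial Adam learning rate.
#' @param patience epochs without validation improvement before the
#'   learning rate is halved.
#' @param freezeMask named logical over parameter tensors (see
#'   [makeFreezeMask()]); \code{NULL} trains everything.
#' @param seed seed controlling batch shuffling.
#' @param verbose print per-epoch losses.
#' @return A list with elements \code{model} (trained) and \code{report}
#'   (per-epoch train/validation loss in ppm, best epoch, final held-in
#'   MAE/RMSE, frozen parameter fraction).
#' @export
trainModel <- function(model, data, valData = NULL, epochs = 30L,
                       batchSize = 16L, lr = 1e-3, patience = 10L,
                       freezeMask = NULL, seed = 1L, verbose = FALSE) {
  .checkData(model, data, "training")
  if (!is.null(valData)) .checkData(model, valData, "validation")
  cfg <- model@config
  if (is.null(freezeMask))
    freezeMask <- stats::setNames(rep(FALSE, length(model@params)),
                                  names(model@params))
  if (!all(names(model@params) %in% names(freezeMask)))
    stop("freezeMask does not cover all parameter tensors")
  if (is.na(model@targetCenter)) {
    ally <- unlist(lapply(data, `[[`, "y"))
    sdy <- stats::sd(ally)
    model <- setTargetScaling(model, mean(ally),
                              if (is.finite(sdy) && sdy > 0) sdy else 1)
  }
  mu <- model@targetCenter; sc <- model@targetScale
  batches <- lapply(data, function(d)
    c(.graphToBatch(d$graph, model@elements), list(y = (d$y - mu) / sc)))
  valBatch <- if (!is.null(valData))
    .assembleEval(valData, model) else NULL

  parentFp <- .fingerprint(model@params)
  lossScale <- if (cfg$loss == "mae") sc else sc^2
  params <- model@params
  state <- .adamInit(params)
  trainLoss <- valLoss <- numeric(epochs)
  best <- list(loss = Inf, epoch = NA_integer_, params = params)
  sinceImprove <- 0L
  set.seed(seed)
  nB <- length(batches)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nB)
    groupsIdx <- split(ord, ceiling(seq_along(ord) / batchSize))
    epLoss <- 0; epN <- 0L
    for (gi in groupsIdx) {
      bb <- .mergeBatches(batches[gi])
      fw <- .forwardCore(params, cfg, bb, keepCache = TRUE)
      resid <- fw$out - bb$y
      l <- .batchLoss(resid, cfg$loss)
      if (!is.finite(l))
        stop("non-finite training loss at epoch ", ep,
             " (lr = ", lr, ", batch of ", length(gi), " molecules); ",
             "reduce the learning rate")
      epLoss <- epLoss + l * length(resid); epN <- epN + length(resid)
      grads <- .backwardCore(params, cfg, bb, fw$cache,
                             .lossGrad(resid, cfg$loss))
      upd <- .adamStep(params, grads, state, lr, freezeMask)
      params <- upd$params; state <- upd$state
    }
    trainLoss[ep] <- (epLoss / epN) * lossScale   # ppm (mae) / ppm^2 (mse)
    vl <- if (is.null(valBatch)) trainLoss[ep] else {
      pr <- .forwardCore(params, cfg, valBatch)$out
      .batchLoss(pr - valBatch$y, cfg$loss) * lossScale
    }
    valLoss[ep] <- vl
    if (vl < best$loss) {
      best <- list(loss = vl, epoch = ep, params = params)
      sinceImprove <- 0L
    } else {
      sinceImprove <- sinceImprove + 1L
      if (sinceImprove >= patience) {
        lr <- lr / 2
        sinceImprove <- 0L
      }
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g",
                      ep, trainLoss[ep], vl, lr))
  }
  model@params <- best$params
  frozenFrac <- .frozenFraction(model, freezeMask)
  model@lineage <- c(model@lineage, list(list(
    parent = parentFp,
    scheme = attr(freezeMask, "scheme") %||% "none",
    dataFingerprint = .fingerprint(lapply(data, `[[`, "y")),
    seed = seed, epochs = epochs, lr0 = lr)))
  ev <- evaluateModel(model, data)
  list(model = model,
       report = list(trainLoss = trainLoss, valLoss = valLoss,
                     bestEpoch = best$epoch, bestValLoss = best$loss,
                     mae = ev[["mae"]], rmse = ev[["rmse"]],
                     frozenFraction = frozenFrac))
}

.frozenFraction <- function(model, freezeMask) {
  sz <- vapply(model@params, length, integer(1))
  sum(sz[names(sz)[freezeMask[names(sz)]]]) / sum(sz)
}

## Merge per-molecule batches (already element-indexed) into one block
## diagonal batch; labels are concatenated in mask order.
.mergeBatches <- function(bl) {
  if (length(bl) == 1L) return(bl[[1L]])
  offs <- 0L
  zIdx <- integer(); edges <- vector("list", length(bl))
  feats <- vector("list", length(bl)); maskIdx <- integer()
  y <- numeric(); sizes <- integer()
  for (k in seq_along(bl)) {
    b <- bl[[k]]
    zIdx <- c(zIdx, b$zIdx)
    edges[[k]] <- b$edges + offs
    feats[[k]] <- b$feats
    maskIdx <- c(maskIdx, b$maskIdx + offs)
    y <- c(y, b$y)
    sizes <- c(sizes, b$sizes)
    offs <- offs + length(b$zIdx)
  }
  list(zIdx = zIdx, edges = do.call(rbind, edges),
       feats = do.call(rbind, feats), maskIdx = maskIdx, y = y,
       sizes = sizes)
}

.assembleEval <- function(data, model) {
  mu <- model@targetCenter; sc <- model@targetScale
  bl <- lapply(data, function(d)
    c(.graphToBatch(d$graph, model@elements), list(y = (d$y - mu) / sc)))
  .mergeBatches(bl)
}

#' Evaluate a model on labelled graphs
#'
#' @param model a trained [ShiftModel-class].
#' @param data list of [labeledGraph()] entries.
#' @return Named numeric vector with elements \code{mae} and \code{rmse}
#'   (ppm); RMSE is always >= MAE.
#' @export
evaluateModel <- function(model, data) {
  .requireScale(model)
  .checkData(model, data, "evaluation")
  bb <- .assembleEval(data, model)
  pr <- .forwardCore(model@params, model@config, bb)$out
  residPpm <- (pr - bb$y) * model@targetScale
  c(mae = mean(abs(residPpm)), rmse = sqrt(mean(residPpm^2)))
}
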