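## Message-passing network with edge updates.
##
## One update block, applied n_update_blocks times to node states H (N x F)
## and edge states E (Ed x B, B = n_basis), reading the directed edge list
## (i = receiver, j = sender):
##
##   edge update   a1 = (H Wi)[i,] + (H Wj)[j,] + E We + b1     (2 hidden layers)
##                 E' = E + ssp(a1) W2 + b2                       (residual)
##   message       filt = ssp(E' Mf1 + mb1) Mf2 + mb2
##                 m_i  = sum_{j in N(i)} H[j,] * filt_ij         (elementwise)
##   node update   H' = H + ssp(m Nu1 + nb1) Nu2 + nb2            (residual)
##
## Masked (target-nucleus) node states then pass through the dense readout;
## the scalar output is mapped to ppm by the stored affine target scaling.
## ssp is the shifted softplus, ssp(0) = 0.  All gradients are hand-derived
## and verified against finite differences in the test suite.

.ssp <- function(x) pmax(x, 0) + log1p(exp(-abs(x))) - log(2)
.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Model configuration
#'
#' @param feature_dim node feature dimension (embedding width).
#' @param n_basis edge feature dimension; must match the RBF expansion used
#'   to build graphs.
#' @param n_update_blocks number of edge-update/message/node-update blocks.
#' @param edge_update_hidden_layers hidden layers per edge-update block
#'   (fixed 2-layer residual blocks; with the default 3 blocks the edge
#'   updating machinery totals six hidden layers).
#' @param readout_layer_widths dense readout widths; the first entry must
#'   equal \code{feature_dim} and the last must be 1.
#' @param activation currently only \code{"ssp"} (shifted softplus).
#' @param loss \code{"mae"} (default) or \code{"mse"}.
#' @param nucleus \code{"H1"} or \code{"C13"}; one model per nucleus.
#' @param seed integer seed for parameter initialisation.
#' @return A validated configuration list of class \code{"modelConfig"}.
#' @export
modelConfig <- function(feature_dim = 256L, n_basis = 256L,
                        n_update_blocks = 3L, edge_update_hidden_layers = 2L,
                        readout_layer_widths = c(feature_dim, 128L, 64L, 1L),
                        activation = "ssp", loss = c("mae", "mse"),
                        nucleus = c("C13", "H1"), seed = 1L) {
  loss <- match.arg(loss)
  nucleus <- match.arg(nucleus)
  if (feature_dim < 1L) stop("feature_dim must be >= 1")
  if (n_update_blocks < 1L) stop("n_update_blocks must be >= 1")
  if (edge_update_hidden_layers != 2L)
    stop("only 2-layer residual edge-update blocks are implemented")
  if (readout_layer_widths[1] != feature_dim)
    stop("first readout width must equal feature_dim")
  if (utils::tail(readout_layer_widths, 1) != 1L)
    stop("last readout width must be 1")
  if (activation != "ssp") stop("unknown activation: ", activation)
  structure(list(
    feature_dim = as.integer(feature_dim), n_basis = as.integer(n_basis),
    n_update_blocks = as.integer(n_update_blocks),
    edge_update_hidden_layers = 2L,
    readout_layer_widths = as.integer(readout_layer_widths),
    activation = activation, loss = loss, nucleus = nucleus,
    seed = as.integer(seed)), class = "modelConfig")
}

.glorot <- function(nin, nout, scale = 1) {
  lim <- scale * sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialise a shift model
#'
#' Deterministic given \code{config$seed}: identical seeds give bitwise
#' identical parameters.  Every tensor is tagged with a functional group
#' label (\code{embedding}, \code{edge_update}, \code{message},
#' \code{node_update}, \code{readout}) used by the freeze schemes.
#'
#' @param config a [modelConfig()].
#' @return A [ShiftModel-class] with untrained parameters and unset target
#'   scaling.
#' @export
#' @examples
#' m <- initModel(modelConfig(feature_dim = 8, n_basis = 8,
#'                            readout_layer_widths = c(8, 4, 1)))
#' m
initModel <- function(config = modelConfig()) {
  stopifnot(inherits(config, "modelConfig"))
  Fd <- config$feature_dim; B <- config$n_basis
  params <- list(); groups <- character()
  add <- function(name, tensor, group) {
    params[[name]] <<- tensor
    groups[[name]] <<- group
  }
  set.seed(config$seed)
  ## unit-variance embedding rows: node states start at O(1) per component
  add("embedding",
      matrix(stats::runif(length(.SUPPORTED_ELEMENTS) * Fd, -sqrt(3), sqrt(3)),
             length(.SUPPORTED_ELEMENTS), Fd),
      "embedding")
  for (t in seq_len(config$n_update_blocks)) {
    pre <- sprintf("block%d.", t)
    add(paste0(pre, "edge.Wi"), .glorot(Fd, Fd), "edge_update")
    add(paste0(pre, "edge.Wj"), .glorot(Fd, Fd), "edge_update")
    add(paste0(pre, "edge.We"), .glorot(B, Fd), "edge_update")
    add(paste0(pre, "edge.b1"), numeric(Fd), "edge_update")
    ## residual-branch output layers (edge.W2, node.W2) and the filter
    ## output (msg.W2) start at 1/10 scale so the stack is near-identity at
    ## initialisation; otherwise the product structure of the messages
    ## (node features times edge-derived filters) compounds across blocks
    ## and the forward signal explodes before any learning happens
    add(paste0(pre, "edge.W2"), .glorot(Fd, B, 0.1), "edge_update")
    add(paste0(pre, "edge.b2"), numeric(B), "edge_update")
    add(paste0(pre, "msg.W1"), .glorot(B, Fd), "message")
    add(paste0(pre, "msg.b1"), numeric(Fd), "message")
    add(paste0(pre, "msg.W2"), .glorot(Fd, Fd, 0.1), "message")
    add(paste0(pre, "msg.b2"), numeric(Fd), "message")
    add(paste0(pre, "node.W1"), .glorot(Fd, Fd), "node_update")
    add(paste0(pre, "node.b1"), numeric(Fd), "node_update")
    add(paste0(pre, "node.W2"), .glorot(Fd, Fd, 0.1), "node_update")
    add(paste0(pre, "node.b2"), numeric(Fd), "node_update")
  }
  w <- config$readout_layer_widths
  for (l in seq_len(length(w) - 1L)) {
    add(sprintf("readout.W%d", l), .glorot(w[l], w[l + 1L]), "readout")
    add(sprintf("readout.b%d", l), numeric(w[l + 1L]), "readout")
  }
  new("ShiftModel", config = unclass(config), params = params,
      groups = groups, nucleus = config$nucleus,
      elements = .SUPPORTED_ELEMENTS,
      targetCenter = NA_real_, targetScale = NA_real_, lineage = list())
}

#' Total and per-group parameter counts
#'
#' @param model a [ShiftModel-class].
#' @return Named integer vector of scalar parameter counts per group, with a
#'   \code{"total"} entry appended.
#' @export
parameterCounts <- function(model) {
  sz <- vapply(modelParams(model), length, integer(1))
  per <- vapply(split(sz, paramGroups(model)[names(sz)]), sum, integer(1))
  c(per, total = sum(sz))
}

## ---- internal batched representation ------------------------------------

## A "batch" is one block-diagonal union of environment graphs:
## zIdx (node element row in the embedding), edges (Ed x 2, receiver/sender),
## feats (Ed x B), maskIdx (rows of H that are prediction targets), and
## graphSizes for bookkeeping.
.graphToBatch <- function(graphs, elements) {
  if (inherits(graphs, "EnvironmentGraph")) graphs <- list(graphs)
  offs <- 0L
  zIdx <- integer(); edges <- matrix(integer(), 0L, 2L)
  feats <- NULL; maskIdx <- integer(); sizes <- integer()
  featList <- vector("list", length(graphs))
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    z <- match(atomElements(g), elements)
    if (anyNA(z))
      stop("graph contains element(s) outside the model's set: ",
           paste(unique(atomElements(g)[is.na(z)]), collapse = ", "))
    zIdx <- c(zIdx, z)
    if (nrow(g@edges)) edges <- rbind(edges, g@edges + offs)
    featList[[k]] <- g@features
    maskIdx <- c(maskIdx, which(targetMask(g)) + offs)
    sizes <- c(sizes, length(z))
    offs <- offs + length(z)
  }
  feats <- do.call(rbind, featList)
  list(zIdx = zIdx, edges = edges, feats = feats, maskIdx = maskIdx,
       sizes = sizes)
}

## rowsum into a fixed number of rows (groups absent from idx give zeros)
.scatterRows <- function(x, idx, n) {
  out <- matrix(0, n, ncol(x))
  if (length(idx)) {
    rs <- rowsum(x, idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

## Forward pass over one batch.  Returns standardised (unit-scale) outputs
## for masked nodes plus, optionally, every intermediate needed by the
## hand-written backward pass.
.forwardCore <- function(params, cfg, batch, keepCache = FALSE) {
  Tn <- cfg$n_update_blocks
  N <- length(batch$zIdx)
  ii <- batch$edges[, 1L]; jj <- batch$edges[, 2L]
  Ed <- length(ii)
  H <- params$embedding[batch$zIdx, , drop = FALSE]
  E <- batch$feats
  blocks <- if (keepCache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    p <- function(s) params[[sprintf("block%d.%s", t, s)]]
    Hin <- H; Eprev <- E
    if (Ed > 0L) {
      Xi <- Hin %*% p("edge.Wi"); Xj <- Hin %*% p("edge.Wj")
      A1 <- Xi[ii, , drop = FALSE] + Xj[jj, , drop = FALSE] +
        Eprev %*% p("edge.We")
      A1 <- sweep(A1, 2L, p("edge.b1"), "+")
      S1 <- .ssp(A1)
      E <- Eprev + sweep(S1 %*% p("edge.W2"), 2L, p("edge.b2"), "+")
      F1 <- sweep(E %*% p("msg.W1"), 2L, p("msg.b1"), "+")
      G1 <- .ssp(F1)
      Filt <- sweep(G1 %*% p("msg.W2"), 2L, p("msg.b2"), "+")
      Me <- Hin[jj, , drop = FALSE] * Filt
      M <- .scatterRows(Me, ii, N)
    } else {
      A1 <- S1 <- F1 <- G1 <- Filt <- NULL
      M <- matrix(0, N, cfg$feature_dim)
    }
    N1 <- sweep(M %*% p("node.W1"), 2L, p("node.b1"), "+")
    P1 <- .ssp(N1)
    H <- Hin + sweep(P1 %*% p("node.W2"), 2L, p("node.b2"), "+")
    if (keepCache)
      blocks[[t]] <- list(Hin = Hin, Eprev = Eprev, A1 = A1, S1 = S1,
                          Enew = E, F1 = F1, G1 = G1, Filt = Filt,
                          M = M, N1 = N1, P1 = P1)
  }
  ## readout on masked nodes
  X <- H[batch$maskIdx, , drop = FALSE]
  w <- cfg$readout_layer_widths
  nl <- length(w) - 1L
  acts <- vector("list", nl + 1L); pres <- vector("list", nl)
  acts[[1L]] <- X
  for (l in seq_len(nl)) {
    Z <- sweep(acts[[l]] %*% params[[sprintf("readout.W%d", l)]], 2L,
               params[[sprintf("readout.b%d", l)]], "+")
    pres[[l]] <- Z
    acts[[l + 1L]] <- if (l < nl) .ssp(Z) else Z
  }
  out <- drop(acts[[nl + 1L]])
  if (!keepCache) return(list(out = out))
  list(out = out,
       cache = list(blocks = blocks, H = H, acts = acts, pres = pres))
}

## Backward pass: dOut is the gradient of the loss w.r.t. the standardised
## readout outputs (one per masked node).  Returns a named gradient list
## congruent with params.
.backwardCore <- function(params, cfg, batch, cache, dOut) {
  Tn <- cfg$n_update_blocks
  N <- length(batch$zIdx)
  ii <- batch$edges[, 1L]; jj <- batch$edges[, 2L]
  Ed <- length(ii)
  grads <- list()
  w <- cfg$readout_layer_widths
  nl <- length(w) - 1L
  dA <- matrix(dOut, ncol = 1L)
  for (l in rev(seq_len(nl))) {
    if (l < nl) dA <- dA * .sigmoid(cache$pres[[l]])
    Wn <- sprintf("readout.W%d", l); bn <- sprintf("readout.b%d", l)
    grads[[Wn]] <- crossprod(cache$acts[[l]], dA)
    grads[[bn]] <- colSums(dA)
    dA <- dA %*% t(params[[Wn]])
  }
  dH <- matrix(0, N, cfg$feature_dim)
  dH[batch$maskIdx, ] <- dA
  dE <- matrix(0, nrow(batch$feats), cfg$n_basis)
  for (t in rev(seq_len(Tn))) {
    cb <- cache$blocks[[t]]
    nm <- function(s) sprintf("block%d.%s", t, s)
    p <- function(s) params[[nm(s)]]
    ## node update: H = Hin + ssp(N1) W2 + b2
    dP2 <- dH                           # gradient w.r.t. the residual branch
    dP1 <- dP2 %*% t(p("node.W2"))
    grads[[nm("node.W2")]] <- crossprod(cb$P1, dP2)
    grads[[nm("node.b2")]] <- colSums(dP2)
    dN1 <- dP1 * .sigmoid(cb$N1)
    grads[[nm("node.W1")]] <- crossprod(cb$M, dN1)
    grads[[nm("node.b1")]] <- colSums(dN1)
    dM <- dN1 %*% t(p("node.W1"))
    dHin <- dH                          # residual path
    if (Ed > 0L) {
      ## message: M = scatter(Hin[jj,] * Filt, ii)
      dMe <- dM[ii, , drop = FALSE]
      dHin <- dHin + .scatterRows(dMe * cb$Filt, jj, N)
      dFilt <- dMe * cb$Hin[jj, , drop = FALSE]
      ## filter net: Filt = ssp(Enew Mf1 + mb1) Mf2 + mb2
      grads[[nm("msg.W2")]] <- crossprod(cb$G1, dFilt)
      grads[[nm("msg.b2")]] <- colSums(dFilt)
      dG1 <- dFilt %*% t(p("msg.W2"))
      dF1 <- dG1 * .sigmoid(cb$F1)
      grads[[nm("msg.W1")]] <- crossprod(cb$Enew, dF1)
      grads[[nm("msg.b1")]] <- colSums(dF1)
      dEnew <- dE + dF1 %*% t(p("msg.W1"))
      ## edge update: Enew = Eprev + ssp(A1) W2 + b2
      dA2 <- dEnew
      grads[[nm("edge.W2")]] <- crossprod(cb$S1, dA2)
      grads[[nm("edge.b2")]] <- colSums(dA2)
      dS1 <- dA2 %*% t(p("edge.W2"))
      dA1 <- dS1 * .sigmoid(cb$A1)
      grads[[nm("edge.b1")]] <- colSums(dA1)
      grads[[nm("edge.We")]] <- crossprod(cb$Eprev, dA1)
      dE <- dEnew + dA1 %*% t(p("edge.We"))
      dXi <- .scatterRows(dA1, ii, N)
      dXj <- .scatterRows(dA1, jj, N)
      grads[[nm("edge.Wi")]] <- crossprod(cb$Hin, dXi)
      grads[[nm("edge.Wj")]] <- crossprod(cb$Hin, dXj)
      dHin <- dHin + dXi %*% t(p("edge.Wi")) + dXj %*% t(p("edge.Wj"))
    } else {
      zF <- function(s) array(0, dim(p(s)))
      for (s in c("msg.W2", "msg.b2", "msg.W1", "msg.b1", "edge.W2",
                  "edge.b2", "edge.b1", "edge.We", "edge.Wi", "edge.Wj"))
        grads[[nm(s)]] <- zF(s)
    }
    dH <- dHin
  }
  grads[["embedding"]] <- .scatterRows(dH, batch$zIdx,
                                       nrow(params$embedding))
  ## vectors were stored as matrices where convenient; coerce to shapes
  for (n in names(grads))
    if (is.null(dim(params[[n]]))) grads[[n]] <- as.numeric(grads[[n]])
  grads
}

## ---- user-facing forward ------------------------------------------------

.requireScale <- function(model) {
  if (is.na(model@targetCenter) || is.na(model@targetScale))
    stop("model has no target scaling yet; train it first or set the ",
         "scaling explicitly with setTargetScaling()")
}

#' Set the affine output scaling of a model
#'
#' Predictions in ppm are \code{center + scale * network_output}.  Training
#' sets this automatically from the labels of the first training stage;
#' setting it manually is only needed for untrained-model experiments.
#'
#' @param model a [ShiftModel-class].
#' @param center,scale numeric scalars (ppm).
#' @return The updated model.
#' @export
setTargetScaling <- function(model, center, scale) {
  stopifnot(is.finite(center), is.finite(scale), scale > 0)
  model@targetCenter <- center
  model@targetScale <- scale
  model
}

#' Predict per-atom chemical shifts for one or more graphs
#'
#' All masked atoms of a graph are predicted simultaneously in one forward
#' pass.  The graph must have been built for the model's nucleus.
#'
#' @param model a trained [ShiftModel-class].
#' @param graphs an [EnvironmentGraph-class] or a list of them.
#' @return A data.frame with columns \code{graph}, \code{atom}
#'   (1-based index), \code{nucleus}, \code{shift} (ppm) and
#'   \code{provenance} (\code{"predicted"}).
#' @export
predictShifts <- function(model, graphs) {
  .requireScale(model)
  if (inherits(graphs, "EnvironmentGraph")) graphs <- list(graphs)
  for (g in graphs)
    if (nucleusOf(g) != nucleusOf(model))
      stop("graph nucleus ", nucleusOf(g), " does not match model nucleus ",
           nucleusOf(model))
  if (any(vapply(graphs, function(g) ncol(g@features), integer(1)) !=
          model@config$n_basis))
    stop("graph RBF dimension does not match the model's n_basis")
  batch <- .graphToBatch(graphs, model@elements)
  if (!length(batch$maskIdx))
    return(data.frame(graph = integer(), atom = integer(),
                      nucleus = character(), shift = numeric(),
                      provenance = character(), stringsAsFactors = FALSE))
  out <- .forwardCore(model@params, model@config, batch)$out
  ppm <- model@targetCenter + model@targetScale * out
  sizes <- batch$sizes
  graphOf <- rep(seq_along(graphs), sizes)[batch$maskIdx]
  offsets <- cumsum(c(0L, sizes))
  data.frame(graph = graphOf,
             atom = batch$maskIdx - offsets[graphOf],
             nucleus = nucleusOf(model),
             shift = ppm,
             provenance = "predicted",
             stringsAsFactors = FALSE)
}
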