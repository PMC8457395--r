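# Shared helpers: small model configurations for fast unit tests, a
# permutation enumerator for brute-force oracles, and random rigid motions.

tinyRBF <- function() rbfParams(n_basis = 12L, delta = 0.3, mu = 0.5,
                                cutoff = 5.0)

tinyConfig <- function(nucleus = "C13", seed = 1L, blocks = 2L) {
  modelConfig(feature_dim = 8L, n_basis = 12L, n_update_blocks = blocks,
              readout_layer_widths = c(8L, 6L, 1L), nucleus = nucleus,
              seed = seed)
}

tinyLabeledSet <- function(n, seed = 1L, nucleus = "C13") {
  labeledSetFromOracle(makeOracleDataset(n, seed = seed), nucleus, tinyRBF())
}

# all permutations of 1..n (n small)
permAll <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permAll(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

randomRotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rigidMotion <- function(xyz) {
  xyz %*% randomRotation() +
    matrix(stats::runif(3, -10, 10), nrow(xyz), 3, byrow = TRUE)
}

# one shared small trained model for tests that need a non-trivial predictor
.testModelCache <- new.env(parent = emptyenv())
tinyTrainedModel <- function() {
  if (is.null(.testModelCache$model)) {
    set.seed(99)
    data <- tinyLabeledSet(40, seed = 5)
    fit <- trainModel(initModel(tinyConfig(seed = 2)), data[1:32], data[33:40],
                      epochs = 8, batchSize = 8, lr = 2e-3, seed = 3)
    .testModelCache$model <- fit$model
    .testModelCache$report <- fit$report
  }
  .testModelCache$model
}
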