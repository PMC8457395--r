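test_that("initialisation is deterministic in the seed and validates config", {
  a <- initModel(tinyConfig(seed = 7))
  b <- initModel(tinyConfig(seed = 7))
  c <- initModel(tinyConfig(seed = 8))
  expect_identical(modelParams(a), modelParams(b))
  expect_false(identical(modelParams(a), modelParams(c)))
  expect_error(modelConfig(feature_dim = 0), "feature_dim")
  expect_error(modelConfig(readout_layer_widths = c(8, 4, 2)), "readout")
  # every tensor carries exactly one group label
  expect_setequal(names(modelParams(a)), names(paramGroups(a)))
  expect_setequal(unique(paramGroups(a)),
                  c("embedding", "edge_update", "message", "node_update",
                    "readout"))
  counts <- parameterCounts(a)
  expect_identical(unname(counts[["total"]]),
                   sum(vapply(modelParams(a), length, integer(1))))
})

test_that("hand-written gradients agree with finite differences", {
  cfg <- modelConfig(feature_dim = 6, n_basis = 7, n_update_blocks = 2,
                     readout_layer_widths = c(6, 5, 1), seed = 3)
  m <- initModel(cfg)
  fx <- makeFixture("butane_anti_gauche")
  g <- buildGraph(fx$conformers[[1]], fx$molecule,
                  rbfParams(n_basis = 7, mu = 0.8, delta = 0.3), "C13")
  batch <- ShiftGNN:::.graphToBatch(g, m@elements)
  set.seed(4)
  y <- rnorm(length(batch$maskIdx))
  lossOf <- function(params)
    mean(abs(ShiftGNN:::.forwardCore(params, cfg, batch)$out - y))
  fw <- ShiftGNN:::.forwardCore(m@params, cfg, batch, keepCache = TRUE)
  grads <- ShiftGNN:::.backwardCore(m@params, cfg, batch, fw$cache,
                                    sign(fw$out - y) / length(y))
  eps <- 1e-6
  for (nm in names(m@params)) {
    idx <- sample(length(m@params[[nm]]), min(3, length(m@params[[nm]])))
    for (i in idx) {
      pp <- m@params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m@params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossOf(pp) - lossOf(pm)) / (2 * eps)
      if (abs(num) > 1e-6)
        expect_lt(abs(num - grads[[nm]][i]) / abs(num), 1e-4)
    }
  }
})

test_that("forward pass respects masks, locality and nucleus separation", {
  m <- setTargetScaling(initModel(tinyConfig()), 100, 5)
  # empty target mask: no predictions
  g0 <- buildGraph(Conformer("x", rbind(c(0, 0, 0), c(1, 0, 0))),
                   Molecule("x", c("O", "N")), tinyRBF(), "C13")
  expect_identical(nrow(predictShifts(m, g0)), 0L)
  # an H1 model never emits predictions for carbon atoms and vice versa
  fx <- makeFixture("methane")
  gH <- buildGraph(fx$conformers[[1]], fx$molecule, tinyRBF(), "H1")
  mH <- setTargetScaling(initModel(tinyConfig(nucleus = "H1")), 5, 1)
  predH <- predictShifts(mH, gH)
  expect_setequal(predH$atom, 2:5)
  expect_error(predictShifts(m, gH), "nucleus")
  # locality: an atom far beyond every message-passing radius changes nothing
  base <- predictShifts(m, buildGraph(fx$conformers[[1]], fx$molecule,
                                      tinyRBF(), "C13"))
  molX <- Molecule("mx", c(atomElements(fx$molecule), "H"))
  confX <- Conformer("mx", rbind(coords(fx$conformers[[1]]), c(40, 0, 0)))
  withX <- predictShifts(m, buildGraph(confX, molX, tinyRBF(), "C13"))
  expect_lt(max(abs(base$shift - withX$shift)), 1e-5)
})

test_that("training descends, returns best-validation weights and freezes on demand", {
  data <- tinyLabeledSet(50, seed = 21)
  m <- initModel(tinyConfig(seed = 5))
  fit <- trainModel(m, data[1:40], data[41:50], epochs = 15, batchSize = 8,
                    lr = 2e-3, seed = 6)
  expect_lt(tail(fit$report$trainLoss, 1), fit$report$trainLoss[1])
  expect_true(fit$report$bestEpoch <= 15)
  expect_true(all(is.finite(fit$report$valLoss)))
  expect_gte(fit$report$rmse, fit$report$mae)
  # all-frozen training returns the input parameters bitwise
  m2 <- setTargetScaling(initModel(tinyConfig(seed = 5)), 100, 5)
  allFrozen <- setNames(rep(TRUE, length(modelParams(m2))),
                        names(modelParams(m2)))
  fit2 <- trainModel(m2, data[1:8], epochs = 2, freezeMask = allFrozen,
                     seed = 1)
  expect_identical(modelParams(fit2$model), modelParams(m2))
  # empty training set errors
  expect_error(trainModel(m, list()), "empty")
})

test_that("evaluation computes MAE and RMSE with their defining formulas", {
  # build a model whose predictions we can control through target scaling:
  # evaluate on synthetic residuals instead via direct formula checks
  m <- tinyTrainedModel()
  data <- tinyLabeledSet(6, seed = 77)
  ev <- evaluateModel(m, data)
  pred <- unlist(lapply(data, function(d)
    predictShifts(m, d$graph)$shift))
  y <- unlist(lapply(data, `[[`, "y"))
  expect_equal(ev[["mae"]], mean(abs(pred - y)), tolerance = 1e-10)
  expect_equal(ev[["rmse"]], sqrt(mean((pred - y)^2)), tolerance = 1e-10)
  expect_gte(ev[["rmse"]], ev[["mae"]])
  expect_error(evaluateModel(m, list()), "empty")
  # hand values: errors (+1, -1) and (0, 2)
  expect_equal(mean(abs(c(1, -1))), 1)
  expect_equal(sqrt(mean(c(0, 2)^2)), sqrt(2))
})

test_that("checkpoints round-trip bitwise including lineage", {
  m <- tinyTrainedModel()
  path <- tempfile(fileext = ".ckpt")
  saveCheckpoint(m, path)
  m2 <- loadCheckpoint(path)
  expect_identical(modelParams(m2), modelParams(m))
  expect_identical(m2@config, m@config)
  expect_identical(m2@lineage, m@lineage)
  expect_identical(m2@targetCenter, m@targetCenter)
  expect_error(loadCheckpoint(tempfile()), "not found")
})
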