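test_that("structure filtering applies charge, weight, element and stereo rules", {
  mols <- list(
    Molecule("ok", c("C", "H", "H", "H", "H")),
    Molecule("cation", c("C", "H", "H", "H"), formalCharges = c(1, 0, 0, 0)),
    Molecule("brominated", c("C", "Br", "H", "H", "H")),
    # 41 carbons + 8 H: MW ~ 500.5 -> rejected by the strict < 500 rule
    Molecule("heavy", c(rep("C", 41), rep("H", 8))),
    # 40 C + 19 H: 499.6 -> kept (boundary, strict <)
    Molecule("boundary", c(rep("C", 40), rep("H", 19))),
    Molecule("undefStereo", c("C", "H", "O", "H"),
             stereoDefined = c(TRUE, FALSE))
  )
  res <- filterStructures(mols, require_stereo_defined = TRUE)
  keptIds <- vapply(res$kept, molId, "")
  expect_setequal(keptIds, c("ok", "boundary"))
  expect_identical(res$reasons[["charge"]], 1L)
  expect_identical(res$reasons[["element"]], 1L)
  expect_identical(res$reasons[["mw"]], 1L)
  expect_identical(res$reasons[["stereo"]], 1L)
  # stereo rule relaxed: the undefined-stereo molecule comes back
  res2 <- filterStructures(mols, require_stereo_defined = FALSE)
  expect_true("undefStereo" %in% vapply(res2$kept, molId, ""))
})

test_that("farthest-neighbour sampling matches a brute-force greedy oracle", {
  set.seed(42)
  fps <- matrix(runif(6 * 32) > 0.5, 6, 32)
  jacc <- function(a, b) {
    u <- sum(a | b); if (u == 0) 0 else 1 - sum(a & b) / u
  }
  # independent naive greedy reimplementation
  oracle <- function(fps, k, seed) {
    n <- nrow(fps)
    set.seed(seed)
    sel <- sample.int(n)[1L]
    while (length(sel) < k) {
      minD <- vapply(seq_len(n), function(i) {
        if (i %in% sel) return(-Inf)
        min(vapply(sel, function(s) jacc(fps[i, ], fps[s, ]), numeric(1)))
      }, numeric(1))
      sel <- c(sel, which(minD == max(minD))[1L])
    }
    sel
  }
  for (seed in 1:4)
    expect_identical(farthestNeighborSample(fps, 3, seed),
                     as.integer(oracle(fps, 3, seed)))
  # degenerate cases
  expect_identical(sort(farthestNeighborSample(fps, 6, 1)), 1:6)
  expect_length(farthestNeighborSample(fps, 1, 3), 1L)
  expect_error(farthestNeighborSample(fps, 7, 1), "exceeds")
  # no duplicates; min pairwise distance non-increasing in k
  sel <- farthestNeighborSample(fps, 6, 2)
  expect_identical(anyDuplicated(sel), 0L)
  minPair <- vapply(2:6, function(k) {
    s <- sel[1:k]
    min(apply(combn(s, 2), 2, function(p) jacc(fps[p[1], ], fps[p[2], ])))
  }, numeric(1))
  expect_true(all(diff(minPair) <= 1e-12))
})

test_that("shielding-to-shift scaling reproduces the tabulated coefficients and is affine", {
  relC <- defaultScaling("C13")
  relH <- defaultScaling("H1")
  expect_equal(scaleShielding(0, relC), 181.40)
  expect_equal(scaleShielding(0, relH), 29.30)
  expect_equal(scaleShielding(100, relC), 181.40 - 97)
  # affine: differences scale with the slope only
  s1 <- runif(5, 0, 200); s2 <- runif(5, 0, 200)
  expect_equal(scaleShielding(s1, relC) - scaleShielding(s2, relC),
               -relC$slope * (s1 - s2))
  expect_error(scalingRelation(1, -0.5))
})

test_that("IQR cleaning keeps ties, removes gross outliers and reports both error metrics", {
  mkTab <- function(shift, prov)
    data.frame(molecule_id = sprintf("m%d", seq_along(shift)), atom = 1L,
               nucleus = "C13", shift = shift, provenance = prov,
               stringsAsFactors = FALSE)
  # all differences equal: IQR 0, inclusive bounds keep everything
  comp <- mkTab(rep(10, 6), "computed"); expt <- mkTab(rep(8, 6), "experimental")
  r <- cleanByIQR(comp, expt)
  expect_true(all(r$kept))
  expect_equal(r$iqr, 0)
  # a gross outlier beyond Q3 + 1.5 IQR is removed
  d <- c(1:100, 1000)
  r2 <- cleanByIQR(mkTab(d, "computed"), mkTab(rep(0, 101), "experimental"))
  q <- quantile(d, c(.25, .75), type = 7)
  expect_equal(r2$lower, unname(q[1] - 1.5 * diff(q)))
  expect_equal(r2$upper, unname(q[2] + 1.5 * diff(q)))
  expect_identical(which(!r2$kept), 101L)
  expect_lt(r2$after[["rmse"]], r2$before[["rmse"]])
  # removed fraction invariant under a constant offset of all differences
  r3 <- cleanByIQR(mkTab(d + 50, "computed"),
                   mkTab(rep(0, 101), "experimental"))
  expect_equal(r3$removedFraction, r2$removedFraction)
  expect_error(cleanByIQR(mkTab(1:3, "computed"),
                          mkTab(1:3, "experimental")), "at least 4")
})

test_that("dataset splits are disjoint, exhaustive and reproducible", {
  ids <- sprintf("mol%04d", 1:1100)
  sp <- splitDataset(ids, 500, 500, seed = 3)
  expect_length(sp$train, 100L)
  expect_length(sp$val, 500L)
  expect_length(sp$test, 500L)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_identical(sp, splitDataset(ids, 500, 500, seed = 3))
  expect_false(identical(sp, splitDataset(ids, 500, 500, seed = 4)))
  expect_error(splitDataset(ids[1:900], 500, 500), "more ids")
})

test_that("fingerprints come back as one bit row per molecule", {
  ents <- list(makeFixture("methane"), makeFixture("butane_anti_gauche"),
               makeFixture("valine_like"))
  fps <- moleculeFingerprints(ents)
  expect_identical(dim(fps), c(3L, 1024L))
  expect_type(fps[1, 1], "logical")
  # methane has a single heavy atom, hence no atom pairs
  expect_identical(sum(fps[1, ]), 0L)
  expect_gt(sum(fps[3, ]), 0L)
})
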