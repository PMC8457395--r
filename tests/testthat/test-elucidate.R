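test_that("sorted matching pairs values positionally after sorting", {
  # identical multisets in different orders align perfectly
  expect_equal(matchSorted(c(30, 10, 20), c(20, 30, 10))$mae, 0)
  # worked arithmetic: sorted pairing (10,12), (20,19)
  r <- matchSorted(c(10, 20), c(19, 12))
  expect_equal(r$mae, 1.5)
  expect_equal(r$pairs$pred, c(10, 20))
  expect_equal(r$pairs$exp, c(12, 19))
  expect_error(matchSorted(numeric(), numeric()), "empty")
  expect_error(matchSorted(c(1, 2), c(1, 2, 3)), "differ in length")
  # permissive mode pairs the best sorted overlap and records the dropped value
  rt <- suppressWarnings(matchSorted(c(1, 2), c(1, 2, 50), allowTruncate = TRUE))
  expect_equal(rt$mae, 0)
  expect_equal(rt$dropped, 50)
})

test_that("candidate ranking orders by MAE and the global mode recovers bijections", {
  exp1 <- c(12.1, 55.4, 128.2)
  cands <- list(good = exp1, bad = exp1 + 5)
  r <- rankCandidates(cands, exp1)
  expect_identical(r[[1]]$candidate_id, "good")
  expect_equal(r[[1]]$mae, 0)
  expect_equal(r[[2]]$mae, 5)
  # single candidate passes through
  r1 <- rankCandidates(cands[1], exp1)
  expect_length(r1, 1L)
  # global assignment beats per-spectrum argmin on a crafted 4x4 instance
  set.seed(8)
  truth <- lapply(1:4, function(i) sort(runif(5, 0, 200)))
  # spectra: each close to its own candidate, but spectrum 1 is slightly
  # closer to candidate 2 than to its own, so greedy argmin misassigns
  spectra <- list(truth[[2]] + 0.1, truth[[2]] + 1, truth[[3]] + 1,
                  truth[[4]] + 1)
  names(truth) <- paste0("cand", 1:4)
  # verify by brute force over all 24 pairings that the DP is optimal
  cost <- outer(1:4, 1:4, Vectorize(function(s, c)
    matchSorted(truth[[c]], spectra[[s]])$mae))
  perms <- permAll(4)
  totals <- apply(perms, 1, function(p) sum(cost[cbind(1:4, p)]))
  best <- perms[which.min(totals), ]
  g <- rankCandidates(truth, spectra, mode = "global")
  expect_equal(match(g$candidate, names(truth)), unname(best))
  expect_equal(attr(g, "totalMAE"), min(totals), tolerance = 1e-12)
})

test_that("optimal reassignment equals the exhaustive permutation minimum", {
  # swapped pair comes back corrected (alpha/beta-carbon style swap)
  r <- optimalReassignment(c(a1 = 128.0, a2 = 150.0),
                           c(a1 = 150.0, a2 = 128.0))
  expect_equal(r$maeAfter, 0)
  expect_equal(unname(r$permutation), c("a2", "a1"))
  expect_true(r$flagged)  # before-MAE 22 > 3.5
  # already optimal: identity permutation
  r2 <- optimalReassignment(c(x = 1, y = 2), c(x = 1.1, y = 2.2))
  expect_identical(unname(r2$permutation), c("x", "y"))
  # random 7-atom instances against the exhaustive 5040-permutation oracle
  perms <- permAll(7)
  set.seed(13)
  for (rep in 1:10) {
    p <- runif(7, 0, 200); e <- runif(7, 0, 200)
    rr <- optimalReassignment(p, e)
    bruteMin <- min(apply(perms, 1, function(pi) mean(abs(p - e[pi]))))
    expect_equal(rr$maeAfter, bruteMin, tolerance = 1e-12)
    expect_lte(rr$maeAfter, rr$maeBefore)
  }
  expect_error(optimalReassignment(1:3, 1:4), "same atom count")
})

test_that("class-constrained reassignment only permutes within classes", {
  p <- c(a = 10, b = 20, c = 100, d = 110)
  e <- c(a = 20, b = 10, c = 110, d = 100)
  rr <- optimalReassignment(p, e, classes = c("lo", "lo", "hi", "hi"))
  expect_equal(rr$maeAfter, 0)
  # with classes forbidding the fix, the swap cannot cross groups
  rr2 <- optimalReassignment(c(a = 10, b = 100), c(a = 100, b = 10),
                             classes = c("x", "y"))
  expect_equal(rr2$maeAfter, rr2$maeBefore)
})

test_that("outlier flagging uses a strict 3.5 ppm default threshold", {
  mk <- function(mae) structure(list(candidate_id = "c", mae = mae),
                                class = "candidateResult")
  expect_length(flagOutliers(list(mk(3.5))), 0L)       # boundary: not flagged
  expect_length(flagOutliers(list(mk(3.500001))), 1L)
  expect_length(flagOutliers(list()), 0L)
  expect_length(flagOutliers(list(mk(1), mk(4), mk(10)), threshold = 3.5), 2L)
})
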