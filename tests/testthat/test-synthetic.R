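test_that("fixtures are valid molecules with the advertised geometry contrasts", {
  for (nm in c("methane", "butane_anti_gauche", "cyclohexane_chair_boat",
               "cis_trans_disub_cyclohexane", "valine_like")) {
    fx <- makeFixture(nm)
    expect_true(validObject(fx$molecule))
    for (cf in fx$conformers) expect_true(validObject(cf))
  }
  expect_error(makeFixture("nonesuch"), "unknown fixture")
  # methane: 5 atoms, carbon at the origin
  me <- makeFixture("methane")
  expect_length(atomElements(me$molecule), 5L)
  expect_equal(coords(me$conformers[[1]])[1, ], c(0, 0, 0))
  # chair/boat: same bonds, C1-C4 transannular distance differs
  cb <- makeFixture("cyclohexane_chair_boat")
  d14 <- vapply(cb$conformers, function(cf)
    sqrt(sum((coords(cf)[1, ] - coords(cf)[4, ])^2)), numeric(1))
  expect_gt(abs(diff(d14)), 0.1)
  # cis/trans pair: identical bond lists, different distance multisets
  ct <- makeFixture("cis_trans_disub_cyclohexane")
  expect_length(ct$conformers, 2L)
  dmult <- lapply(ct$conformers, function(cf) sort(dist(coords(cf))))
  expect_gt(max(abs(dmult[[1]] - dmult[[2]])), 0.1)
  # bonded distances all match plausible covalent lengths in both geometries
  b <- bondTable(ct$molecule)
  for (cf in ct$conformers) {
    bl <- sqrt(rowSums((coords(cf)[b[, 1], ] - coords(cf)[b[, 2], ])^2))
    expect_true(all(bl > 0.9 & bl < 1.6))
  }
})

test_that("oracle labels follow the declared closed form", {
  op <- oracleParams()
  # isolated atom: base shift exactly
  iso <- oracleShifts(Conformer("x", matrix(0, 1, 3)), Molecule("x", "C"), op)
  expect_equal(iso$shift, op$b[["C"]])
  # two-atom system at distance d: pocket-calculator check
  d <- 1.3
  two <- oracleShifts(Conformer("x", rbind(c(0, 0, 0), c(d, 0, 0))),
                      Molecule("x", c("C", "H")), op)
  expect_equal(two$shift[two$nucleus == "C13"],
               op$b[["C"]] + op$c_coef[["H"]] * exp(-d / op$lambda),
               tolerance = 1e-12)
  expect_equal(two$shift[two$nucleus == "H1"],
               op$b[["H"]] + op$c_coef[["C"]] * exp(-d / op$lambda),
               tolerance = 1e-12)
  # beyond the cutoff the neighbour does not contribute
  far <- oracleShifts(Conformer("x", rbind(c(0, 0, 0), c(6, 0, 0))),
                      Molecule("x", c("C", "H")), op)
  expect_equal(far$shift[far$nucleus == "C13"], op$b[["C"]])
})

test_that("oracle labels are rigid-motion invariant and geometry sensitive", {
  fx <- makeFixture("cis_trans_disub_cyclohexane")
  sCis <- oracleShifts(fx$conformers$cis, fx$molecule)
  sTrans <- oracleShifts(fx$conformers$trans, fx$molecule)
  # identical 2D graphs, distinct label vectors
  expect_gt(max(abs(sCis$shift - sTrans$shift)), 0.5)
  set.seed(3)
  for (i in 1:100) {
    moved <- Conformer("dm-cyclohexane", rigidMotion(coords(fx$conformers$cis)))
    sM <- oracleShifts(moved, fx$molecule)
    expect_lt(max(abs(sM$shift - sCis$shift)), 1e-9)
  }
})

test_that("contaminated pair generation is seeded and plants the exact outlier count", {
  cp <- makeContaminatedPairs(10000, sigma = 2, outlier_frac = 0.05,
                              outlier_mag = 15, seed = 7)
  expect_length(cp$outlierIdx, 500L)
  expect_identical(nrow(cp$computed), 10000L)
  cp2 <- makeContaminatedPairs(10000, sigma = 2, outlier_frac = 0.05,
                               outlier_mag = 15, seed = 7)
  expect_identical(cp, cp2)
  # no contamination: all differences within 6 sigma (seeded check)
  clean <- makeContaminatedPairs(5000, sigma = 2, outlier_frac = 0,
                                 seed = 11)
  expect_true(all(abs(clean$computed$shift - clean$experimental$shift) < 12))
  expect_error(makeContaminatedPairs(100, outlier_frac = 0.6), "outlier_frac")
})

test_that("fixture export writes SDF and label files the readers accept", {
  dir <- tempfile("fx")
  writeFixtures(dir)
  sdfs <- list.files(dir, pattern = "\\.sdf$")
  expect_length(sdfs, 5L)
  ent <- readStructures(file.path(dir, "cyclohexane_chair_boat.sdf"), "sdf")
  expect_length(ent, 2L)
  lab <- parseShiftTable(file.path(dir, "oracle_shifts.csv"))
  expect_true(all(lab$nucleus %in% c("H1", "C13")))
  expect_gt(nrow(lab), 50)
  unlink(dir, recursive = TRUE)
})
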