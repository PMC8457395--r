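test_that("SDF write/read round-trips structures, charges, energies and annotations", {
  fx <- makeFixture("butane_anti_gauche")
  sh <- oracleShifts(fx$conformers$anti, fx$molecule)
  path <- tempfile(fileext = ".sdf")
  writeStructuresSDF(fx$molecule, fx$conformers, path, shifts = sh)
  ent <- readStructures(path, "sdf")
  expect_length(ent, 2L)
  m <- ent[[1]]$molecule
  # atom order preserved: coordinate row k maps to atom k
  expect_identical(atomElements(m), atomElements(fx$molecule))
  expect_lt(max(abs(coords(ent[[1]]$conformers[[1]]) -
                    coords(fx$conformers$anti))), 1e-3)
  expect_identical(unname(bondTable(m)), unname(bondTable(fx$molecule)))
  expect_equal(relEnergy(ent[[1]]$conformers[[1]]), 0)
  # embedded shift property block comes back as records
  got <- ent[[1]]$shifts
  expect_identical(nrow(got), nrow(sh))
  expect_lt(max(abs(sort(got$shift) - sort(sh$shift))), 1e-5)
  # formal charges survive via M CHG lines
  ion <- Molecule("ion", c("N", "H", "H", "H", "H"),
                  bonds = cbind(1L, 2:5, 1L),
                  formalCharges = c(1L, 0L, 0L, 0L, 0L))
  xyz <- rbind(c(0, 0, 0), diag(3), c(1, 1, 1) / sqrt(3))
  p2 <- tempfile(fileext = ".sdf")
  writeStructuresSDF(ion, list(Conformer("ion", xyz)), p2)
  back <- readStructures(p2, "sdf")[[1]]$molecule
  expect_identical(formalCharges(back), c(1L, 0L, 0L, 0L, 0L))
  # stereo annotation round-trip
  v <- makeFixture("valine_like")
  p3 <- tempfile(fileext = ".sdf")
  writeStructuresSDF(v$molecule, v$conformers, p3)
  expect_identical(stereoDefined(readStructures(p3, "sdf")[[1]]$molecule),
                   TRUE)
})

test_that("SMILES input yields explicit-hydrogen molecules without conformers", {
  path <- tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "C methane"), path)
  ent <- readStructures(path, "smiles")
  expect_length(ent, 2L)
  tab <- table(atomElements(ent[[1]]$molecule))
  expect_identical(as.integer(tab[c("C", "H", "O")]), c(2L, 6L, 1L))
  expect_identical(molId(ent[[1]]$molecule), "ethanol")
  expect_length(ent[[1]]$conformers, 0L)
  expect_length(atomElements(ent[[2]]$molecule), 5L)
})

test_that("XYZ frames parse into bond-free molecules", {
  path <- tempfile(fileext = ".xyz")
  writeLines(c("3", "water frame", "O 0 0 0", "H 0.96 0 0",
               "H -0.24 0.93 0"), path)
  ent <- readStructures(path, "xyz")
  expect_length(ent, 1L)
  expect_identical(atomElements(ent[[1]]$molecule), c("O", "H", "H"))
  expect_identical(nrow(bondTable(ent[[1]]$molecule)), 0L)
  expect_equal(coords(ent[[1]]$conformers[[1]])[2, 1], 0.96)
})

test_that("degenerate and malformed structure inputs behave as documented", {
  empty <- tempfile(); file.create(empty)
  expect_identical(readStructures(empty, "sdf"), list())
  expect_error(readStructures(tempfile(), "sdf"), "not found")
  # element outside the supported set: retained, flagged
  br <- Molecule("brmol", c("C", "Br", "H", "H", "H"),
                 bonds = cbind(1L, 2:5, 1L))
  p <- tempfile(fileext = ".sdf")
  writeStructuresSDF(br, list(Conformer("brmol",
    rbind(c(0, 0, 0), c(1.9, 0, 0), c(-0.6, 0.9, 0), c(-0.6, -0.9, 0.6),
          c(-0.6, -0.4, -1)))), p)
  expect_warning(ent <- readStructures(p, "sdf"), "outside the supported")
  expect_identical(molId(ent[[1]]$molecule), "brmol")
})

test_that("shift tables parse, validate and round-trip to 1e-6 ppm", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("molecule_id,atom_index,nucleus,shift_ppm,provenance",
               "m1,0,C13,128.5,experimental",
               "m1,1,H1,7.26,experimental"), path)
  rec <- parseShiftTable(path)
  expect_identical(nrow(rec), 2L)
  expect_identical(rec$atom, c(1L, 2L))     # 0-based on disk, 1-based here
  expect_identical(rec$nucleus[1], "C13")
  expect_equal(rec$shift[1], 128.5)
  # header-only file: empty table
  writeLines("molecule_id,atom_index,nucleus,shift_ppm,provenance", path)
  expect_identical(nrow(parseShiftTable(path)), 0L)
  # duplicates error naming the key (with the on-disk 0-based index)
  writeLines(c("molecule_id,atom_index,nucleus,shift_ppm,provenance",
               "m1,0,C13,128.5,experimental",
               "m1,0,C13,129.0,experimental"), path)
  expect_error(parseShiftTable(path), "m1\\|0\\|C13")
  # non-numeric shift and unknown nucleus are row-level errors
  writeLines(c("molecule_id,atom_index,nucleus,shift_ppm,provenance",
               "m1,0,C13,abc,experimental"), path)
  expect_error(parseShiftTable(path), "non-numeric")
  writeLines(c("molecule_id,atom_index,nucleus,shift_ppm,provenance",
               "m1,0,N15,100,experimental"), path)
  expect_error(parseShiftTable(path), "nucleus")
  # prediction round trip through the writer
  preds <- data.frame(molecule_id = "m9", atom = c(3L, 5L), nucleus = "C13",
                      shift = c(12.345678, 99.999999),
                      provenance = "predicted", stringsAsFactors = FALSE)
  out <- tempfile(fileext = ".csv")
  writePredictions(preds, out)
  back <- parseShiftTable(out)
  expect_identical(back$atom, preds$atom)
  expect_lt(max(abs(back$shift - preds$shift)), 1e-6)
  # empty prediction set gives a header-only file
  writePredictions(preds[0, ], out)
  expect_identical(nrow(parseShiftTable(out)), 0L)
  # provenance contract
  preds$provenance <- "computed"
  expect_error(writePredictions(preds, out), "predicted")
})

test_that("annotated SDF output embeds per-atom shift blocks", {
  fx <- makeFixture("methane")
  preds <- data.frame(molecule_id = "methane", atom = 1L, nucleus = "C13",
                      shift = 42.42, provenance = "predicted",
                      stringsAsFactors = FALSE)
  out <- tempfile(fileext = ".sdf")
  writePredictions(preds, out, fmt = "sdf_annotated",
                   structures = list(list(molecule = fx$molecule,
                                          conformers = fx$conformers)))
  back <- readStructures(out, "sdf")[[1]]$shifts
  expect_equal(back$shift[back$nucleus == "C13"], 42.42, tolerance = 1e-6)
})
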