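tables <- loadAminoAcidTables()

test_that("packaged amino-acid tables load with the documented shapes", {
  expect_s4_class(tables, "AminoAcidTables")
  expect_identical(dim(tables@physChem), c(20L, 7L))
  expect_identical(dim(tables@ssEndpoint), c(20L, 11L))
  expect_identical(dim(tables@contactPotential), c(20L, 40L))
})

test_that("amino-acid features have width 78 with a one-hot indicator block", {
  f <- aaFeatures("ACDWY", tables)
  expect_identical(dim(f), c(5L, 78L))
  ind <- f[, 1:20]
  expect_equal(unname(rowSums(ind)), rep(1, 5))
  expect_equal(sum(ind == 1), 5)
  ## table lookups are plain row lookups
  expect_equal(unname(f[1, 21:27]), unname(tables@physChem["A", ]))
  expect_equal(unname(f[4, 39:78]), unname(tables@contactPotential["W", ]))
})

test_that("unknown residue X gets a zero indicator and column-mean lookups", {
  f <- aaFeatures("AXA", tables)
  expect_equal(unname(rowSums(f[, 1:20])), c(1, 0, 1))
  expect_equal(unname(f[2, 21:27]), unname(colMeans(tables@physChem)))
  ## rare letters collapse to X; anything else errors with its position
  expect_equal(unname(aaFeatures("ABA", tables)), unname(aaFeatures("AXA", tables)))
  expect_error(aaFeatures("A1C", tables), "position 2")
})

test_that("evolution features are width 40 with sigmoid-squashed PSSM scores", {
  pssm <- matrix(0, 3, 20, dimnames = list(NULL, NULL))
  hhm <- matrix(1 / 20, 3, 20)
  prof <- SequenceProfile(pssm, hhm)
  f <- evoFeatures(prof)
  expect_identical(dim(f), c(3L, 40L))
  expect_equal(unname(f[, 1:20]), matrix(0.5, 3, 20))  # sigmoid(0)
  expect_equal(unname(f[, 21:40]), unname(hhm))
  ## hand-computed squash on a toy row
  prof2 <- SequenceProfile(matrix(c(-2, 0, 3, rep(0, 57)), 3, 20), hhm)
  f2 <- evoFeatures(prof2)
  expect_equal(unname(f2[1:3, 1]), 1 / (1 + exp(-c(-2, 0, 3))), tolerance = 1e-12)
  expect_equal(unname(evoFeatures(prof2, squash = "none")[1, 1]), -2)
})

test_that("structure features are width 11 and reject non-probability rows", {
  ss8 <- matrix(1 / 8, 4, 8)
  acc3 <- matrix(1 / 3, 4, 3)
  f <- structFeatures(StructurePrediction(ss8, acc3))
  expect_identical(dim(f), c(4L, 11L))
  expect_equal(unname(f[, 1:8]), unname(ss8))
  bad <- ss8; bad[2, ] <- bad[2, ] / 2
  expect_error(StructurePrediction(bad, acc3), "row 2")
})

test_that("assembly produces the documented widths per feature-class mode", {
  L <- 6
  seqs <- paste(rep("A", L), collapse = "")
  prof <- SequenceProfile(matrix(0, L, 20), matrix(1 / 20, L, 20))
  sp <- StructurePrediction(matrix(1 / 8, L, 8), matrix(1 / 3, L, 3))
  full <- assembleFeatures(seqs, tables, prof, sp)
  expect_identical(ncol(full), 129L)
  expect_identical(ncol(assembleFeatures(seqs, tables, classes = "ami")), 78L)
  expect_identical(ncol(assembleFeatures(seqs, tables, prof, classes = "evo")), 40L)
  expect_identical(ncol(assembleFeatures(seqs, tables, struct = sp,
                                         classes = "struct")), 11L)
  expect_identical(ncol(assembleFeatures(seqs, tables, prof, sp,
                                         classes = c("evo", "struct"))), 51L)
  ## column names form the manifest with class prefixes
  expect_true(all(grepl("^(ami|evo|struct)_", colnames(full))))
  expect_identical(sum(grepl("^ami_", colnames(full))), 78L)
  ## missing inputs are refused, never zero-filled
  expect_error(assembleFeatures(seqs, tables), "profile")
  expect_error(assembleFeatures(seqs, tables, prof), "structure")
  ## length disagreement caught
  shortProf <- SequenceProfile(matrix(0, 3, 20), matrix(1 / 20, 3, 20))
  expect_error(assembleFeatures(seqs, tables, shortProf, sp), "residues")
})

test_that("feature assembly is deterministic", {
  prof <- SequenceProfile(matrix(rnorm(40), 2, 20), matrix(1 / 20, 2, 20))
  sp <- StructurePrediction(matrix(1 / 8, 2, 8), matrix(1 / 3, 2, 3))
  a <- assembleFeatures("MK", tables, prof, sp)
  b <- assembleFeatures("MK", tables, prof, sp)
  expect_identical(a, b)
})
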