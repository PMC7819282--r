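test_that("SMILES tables round-trip and count parse failures without raising", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "mols.csv")

  df <- data.frame(id = c("a", "b", "c"),
                   smiles = c("CCO", "c1ccccc1", "CC(=O)O"),
                   logP = c(-0.31, 2.13, -0.17))
  write.csv(df, p, row.names = FALSE)
  ms <- readSmilesTable(p, "smiles", "logP", "id")
  expect_s4_class(ms, "MoleculeSet")
  expect_length(ms, 3L)
  expect_equal(nFailed(ms), 0L)
  expect_equal(unname(molTargets(ms)), df$logP)

  ## one poisoned row: dropped and counted, not an error
  df2 <- rbind(df, data.frame(id = "d", smiles = "not_a_smiles", logP = 1))
  write.csv(df2, p, row.names = FALSE)
  expect_message(ms2 <- readSmilesTable(p, "smiles", "logP", "id"), "failed")
  expect_length(ms2, 3L)
  expect_equal(nFailed(ms2), 1L)
  expect_equal(ms2@failed$id, "d")

  ## written-then-reread synthetic table reproduces ids and targets exactly
  syn <- testDataset(n = 50L)
  p2 <- file.path(tmp, "syn.csv")
  writeSmilesTable(syn, p2)
  back <- readSmilesTable(p2, "smiles", propertyName(syn), "id")
  expect_identical(molIds(back), molIds(syn))
  expect_identical(unname(molSmiles(back)), unname(molSmiles(syn)))
  expect_equal(unname(molTargets(back)), unname(molTargets(syn)),
               tolerance = 1e-12)
  expect_equal(nFailed(back) + length(back), length(syn))
})

test_that("missing files and missing columns are fatal configuration errors", {
  expect_error(readSmilesTable("/nonexistent/file.csv"), "not found")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), tmp, row.names = FALSE)
  expect_error(readSmilesTable(tmp, "smiles"), "missing column")
})

test_that("SDF datasets carry targets in data fields and round-trip", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "mols.sdf")
  ms <- MoleculeSet(smiles = c("CCO", "c1ccccc1"), target = c(-0.31, NA),
                    ids = c("a", "b"), propertyName = "logP")
  writeSdfDataset(ms, p)
  back <- readSdfDataset(p, "logP")
  expect_length(back, 2L)
  expect_equal(unname(molTargets(back))[1], -0.31, tolerance = 1e-12)
  ## block without the field keeps the record with an absent target
  expect_true(is.na(unname(molTargets(back))[2]))

  syn <- testDataset(n = 30L)
  p2 <- file.path(tmp, "syn.sdf")
  writeSdfDataset(syn, p2)
  back2 <- readSdfDataset(p2, propertyName(syn))
  expect_identical(molIds(back2), molIds(syn))
  expect_equal(unname(molTargets(back2)), unname(molTargets(syn)),
               tolerance = 1e-12)
})

test_that("complex reader deletes waters and monoatomic metal ions", {
  tmp <- withr::local_tempdir()
  lig <- data.frame(element = c("C", "C", "O"),
                    x = c(0, 1.5, 2.9), y = 0, z = 0)
  prot <- data.frame(element = c("C", "N", "O", "ZN", "O"),
                     resname = c("ALA", "ALA", "SER", "ZN", "HOH"),
                     x = c(3, 4, 5, 3.5, 3.2), y = 1, z = 0)
  cr <- ComplexRecord("toy", lig, prot, target = 6.1)
  paths <- writeComplex(cr, tmp)
  back <- readComplex(paths[["protein"]], paths[["ligand"]], id = "toy")
  expect_equal(nrow(back@ligandAtoms), 3L)
  ## water oxygen and lone Zn removed; 3 ordinary protein atoms survive
  expect_equal(nrow(back@proteinAtoms), 3L)
  expect_false(any(back@proteinAtoms$resname %in% c("HOH", "ZN")))
  ## coordinates preserved to PDB precision
  expect_equal(back@proteinAtoms$x, prot$x[1:3], tolerance = 1e-3)

  ## empty ligand is fatal
  empty <- file.path(tmp, "empty.pdb")
  writeLines("END", empty)
  expect_error(readComplex(paths[["protein"]], empty), "ligand|PDB|atom")
})

test_that("synthetic complexes round-trip through the PDB writer/reader", {
  crs <- genComplexes(3, seed = 5)
  tmp <- withr::local_tempdir()
  for (cr in crs) {
    paths <- writeComplex(cr, tmp)
    back <- readComplex(paths[["protein"]], paths[["ligand"]], id = cr@id)
    expect_equal(nrow(back@ligandAtoms), nrow(cr@ligandAtoms))
    ## waters + metal are generated, then removed at read time
    nRemoved <- sum(cr@proteinAtoms$resname %in% c("HOH", "ZN"))
    expect_equal(nrow(back@proteinAtoms), nrow(cr@proteinAtoms) - nRemoved)
    keptCoords <- cr@proteinAtoms[!cr@proteinAtoms$resname %in% c("HOH", "ZN"), ]
    expect_equal(back@proteinAtoms$x, keptCoords$x, tolerance = 1e-3)
    expect_equal(back@proteinAtoms$z, keptCoords$z, tolerance = 1e-3)
  }
})

test_that("fingerprint matrices round-trip with their JSON sidecar", {
  tmp <- withr::local_tempdir()
  fx <- testFeatures(n = 30L)
  prefix <- file.path(tmp, "feat")
  writeFingerprintSet(fx$fps, prefix, targets = molTargets(fx$ms))
  back <- readFingerprintSet(prefix)
  expect_identical(unname(back$fps@bits), unname(fx$fps@bits))
  expect_identical(rownames(back$fps@bits), rownames(fx$fps@bits))
  expect_equal(back$fps@layout$block, fx$fps@layout$block)
  expect_equal(unname(back$targets), unname(molTargets(fx$ms)),
               tolerance = 1e-12)
})
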