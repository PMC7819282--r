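test_that("MACCS keys match an independent reference engine bit-for-bit", {
  panel <- rdkitMaccsPanel()
  fps <- maccsKeys(vapply(panel, `[[`, character(1), "smiles"))
  m <- fpMatrix(fps)
  expect_equal(ncol(m), 166L)
  for (k in seq_along(panel))
    expect_equal(which(m[k, ] == 1L), panel[[k]]$bits,
                 info = names(panel)[k])
})

test_that("fingerprints are invariant to SMILES spelling and explicit hydrogens", {
  ## methane with and without explicit hydrogens
  expect_identical(unname(fpMatrix(maccsKeys("C"))),
                   unname(fpMatrix(maccsKeys("[H]C([H])([H])[H]"))))
  ## two spellings of ethanol, and an atom-permuted aromatic
  for (pair in list(c("CCO", "OCC"), c("c1ccccc1O", "Oc1ccccc1"),
                    c("CC(=O)O", "OC(C)=O"))) {
    expect_identical(unname(fpMatrix(ecfp(pair[1]))),
                     unname(fpMatrix(ecfp(pair[2]))), info = pair[1])
    expect_identical(unname(fpMatrix(maccsKeys(pair[1]))),
                     unname(fpMatrix(maccsKeys(pair[2]))), info = pair[1])
  }
})

test_that("ECFP has the configured length and radius-0 bits nest inside radius-2", {
  smis <- c("CC(=O)Oc1ccccc1C(=O)O", "CN1CCC[C@H]1c1cccnc1", "CCOCC")
  e2 <- fpMatrix(ecfp(smis))
  expect_equal(ncol(e2), 2048L)
  expect_true(all(e2 %in% c(0L, 1L)))
  e0 <- fpMatrix(ecfp(smis, fingerprintSpec("ecfp", ecfpRadius = 0)))
  for (k in seq_along(smis))
    expect_true(all(which(e0[k, ] == 1L) %in% which(e2[k, ] == 1L)),
                info = smis[k])
  ## folding: 1024-bit output equals OR of the two 2048-bit halves
  e1024 <- fpMatrix(ecfp(smis, fingerprintSpec("ecfp", ecfpNbits = 1024)))
  manual <- (e2[, 1:1024] | e2[, 1025:2048]) * 1L
  expect_identical(unname(e1024), unname(manual))
})

test_that("conjoint concatenation preserves and recovers its components", {
  smis <- c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O")
  fm <- maccsKeys(smis)
  fe <- ecfp(smis)
  fc <- fpConcat(fm, fe)
  expect_equal(ncol(fpMatrix(fc)), 166L + 2048L)
  expect_equal(fpScheme(fc), "conjoint")
  lay <- fpLayout(fc)
  expect_equal(lay$block, c("maccs", "ecfp"))
  ## slicing the conjoint matrix recovers both inputs exactly
  expect_identical(fpMatrix(fc)[, lay$start[1]:lay$end[1]], fpMatrix(fm))
  expect_identical(fpMatrix(fc)[, lay$start[2]:lay$end[2]], fpMatrix(fe))
  ## single-element concatenation is the identity on the bits
  expect_identical(fpMatrix(fpConcat(fm)), fpMatrix(fm))
  ## featurize() with the conjoint spec gives the same result
  expect_identical(fpMatrix(featurize(smis)), fpMatrix(fc))
})

test_that("pocket extraction applies the closed <= cutoff rule", {
  lig <- data.frame(element = "C", x = 0, y = 0, z = 0)
  prot <- data.frame(element = c("C", "C"), resname = "ALA",
                     x = c(4.0, 5.0), y = 0, z = 0)
  cr <- ComplexRecord("t", lig, prot)
  pk <- extractPocket(cr, 4.5)
  expect_equal(nrow(pk@proteinAtoms), 1L)
  expect_equal(pk@proteinAtoms$x, 4.0)
  ## boundary is closed: an atom exactly at the cutoff is retained
  expect_equal(nrow(extractPocket(cr, 4.0)@proteinAtoms), 1L)
  ## vanishing cutoff with no overlapping atoms leaves an empty pocket
  expect_equal(nrow(extractPocket(cr, 1e-4)@proteinAtoms), 0L)
})

test_that("pocket extraction agrees with the brute-force all-pairs oracle", {
  crs <- genComplexes(6, seed = 9)
  for (cr in crs) {
    for (cutoff in c(3, 4.5, 6)) {
      keep <- bruteForcePocket(cr, cutoff)
      pk <- extractPocket(cr, cutoff)
      expect_equal(nrow(pk@proteinAtoms), sum(keep), info = cr@id)
      expect_equal(pk@proteinAtoms$x, cr@proteinAtoms$x[keep], info = cr@id)
    }
  }
})

test_that("complex featurization lays out ligand blocks before pocket blocks", {
  cr <- genComplexes(1, seed = 4)[[1]]
  fm <- featurizeComplex(cr, fingerprintSpec("maccs"))
  expect_equal(ncol(fpMatrix(fm)), 332L)
  expect_equal(fpLayout(fm)$block, c("ligand.maccs", "pocket.maccs"))
  fc <- featurizeComplex(cr)
  expect_equal(ncol(fpMatrix(fc)), 2L * (166L + 2048L))
  expect_equal(fpLayout(fc)$block,
               c("ligand.maccs", "ligand.ecfp", "pocket.maccs", "pocket.ecfp"))
  ## ligand blocks agree with fingerprinting the ligand alone through the
  ## same 3D perception path regardless of the pocket
  ligOnly <- ComplexRecord(cr@id, cr@ligandAtoms,
                           target = cr@target)
  expect_warning(f0 <- featurizeComplex(ligOnly), "empty pocket")
  lay <- fpLayout(f0)
  pocketCols <- unlist(lapply(grep("^pocket", lay$block), function(k)
    lay$start[k]:lay$end[k]))
  expect_true(all(fpMatrix(f0)[, pocketCols] == 0L))
  ligCols <- unlist(lapply(grep("^ligand", lay$block), function(k)
    lay$start[k]:lay$end[k]))
  expect_identical(fpMatrix(f0)[, ligCols],
                   fpMatrix(fc)[, ligCols])
})

test_that("SlogP reproduces reference Wildman-Crippen values and is additive", {
  vals <- slogP(slogpPanelSmiles())
  expect_equal(unname(vals), unname(rdkitSlogpPanel()), tolerance = 1e-3)
  ## permutation invariance
  expect_equal(unname(slogP("CCOc1ccccc1")), unname(slogP("c1ccccc1OCC")),
               tolerance = 1e-9)
  ## additivity over disconnected fragments
  expect_equal(unname(slogP("CCO.c1ccccc1")),
               unname(slogP("CCO")) + unname(slogP("c1ccccc1")),
               tolerance = 1e-6)
})

test_that("Murcko scaffolds strip side chains and empty out acyclic molecules", {
  s <- murckoScaffold(c("CCc1ccccc1O", "c1ccccc1", "CCO", "CCCCCC"))
  expect_equal(unname(s[1]), unname(s[2]))   # toluene-like side chains pruned
  expect_equal(unname(s[3]), "")
  expect_equal(unname(s[4]), "")
  ## linked ring systems keep their linker
  s2 <- murckoScaffold(c("c1ccccc1CCc1ccncc1", "Cc1ccccc1CCc1ccncc1C"))
  expect_equal(unname(s2[1]), unname(s2[2]))
  expect_true(nzchar(s2[1]))
})

test_that("fingerprint spec validation rejects malformed parameters", {
  expect_error(fingerprintSpec("maccs", ecfpNbits = 1000), "power of two")
  expect_error(fingerprintSpec("bogus"), "scheme")
  expect_error(fingerprintSpec("ecfp", ecfpRadius = 9), "ecfpRadius")
})
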