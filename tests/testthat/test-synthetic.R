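test_that("generated molecules are valid, unique-id'd and reproducible", {
  cfg <- syntheticConfig(nMolecules = 100L, seed = 3L)
  ms <- genMolecules(cfg)
  expect_length(ms, 100L)
  expect_equal(anyDuplicated(molIds(ms)), 0L)
  ## every emitted SMILES parses (featurization would fail otherwise)
  expect_equal(ncol(fpMatrix(maccsKeys(ms))), 166L)
  ## determinism
  ms2 <- genMolecules(syntheticConfig(nMolecules = 100L, seed = 3L))
  expect_identical(unname(molSmiles(ms)), unname(molSmiles(ms2)))
  expect_false(identical(unname(molSmiles(ms)),
                         unname(molSmiles(genMolecules(
                           syntheticConfig(nMolecules = 100L, seed = 4L))))))
})

test_that("the pool yields enough scaffold diversity for scaffold splitting", {
  ms <- genMolecules(syntheticConfig(nMolecules = 200L, seed = 8L))
  nScaffolds <- length(unique(murckoScaffold(ms)))
  expect_gte(nScaffolds, 20L)
})

test_that("noiseless targets are an exact linear function of the planted bits", {
  ms0 <- genMolecules(syntheticConfig(nMolecules = 80L, seed = 5L))
  cfg <- syntheticConfig(nMolecules = 80L, noiseSd = 0, seed = 5L)
  ms <- genTargets(ms0, cfg)
  sig <- ms@metadata$signal
  Xm <- fpMatrix(maccsKeys(ms)); Xe <- fpMatrix(ecfp(ms))
  manual <- drop(Xm[, sig$bitsMaccs] %*% sig$effectsMaccs +
                 Xe[, sig$bitsEcfp] %*% sig$effectsEcfp)
  expect_equal(unname(molTargets(ms)), unname(manual), tolerance = 1e-12)
  ## a linear model on the conjoint bits recovers it to numerical precision
  X <- cbind(Xm[, sig$bitsMaccs], Xe[, sig$bitsEcfp])
  fit <- lm.fit(cbind(1, X), unname(molTargets(ms)))
  expect_lt(sqrt(mean(fit$residuals^2)), 1e-6)
})

test_that("a single planted bit with zero noise gives a two-level target", {
  ms0 <- genMolecules(syntheticConfig(nMolecules = 60L, seed = 6L))
  Xm <- fpMatrix(maccsKeys(ms0))
  prev <- colMeans(Xm)
  bit <- which(prev >= 0.3 & prev <= 0.7)[1]
  cfg <- syntheticConfig(nMolecules = 60L, noiseSd = 0, seed = 6L,
                         signalBitsMaccs = bit, signalBitsEcfp = integer(0),
                         effectSizes = 1)
  ms <- genTargets(ms0, cfg)
  lev <- sort(unique(unname(molTargets(ms))))
  expect_equal(lev, c(0, 1))
})

test_that("splitting signal across blocks makes standalone linear fits strictly worse", {
  ms0 <- genMolecules(syntheticConfig(nMolecules = 300L, seed = 12L))
  cfg <- syntheticConfig(nMolecules = 300L, noiseSd = 0, seed = 12L)
  ms <- genTargets(ms0, cfg)
  sig <- ms@metadata$signal
  y <- unname(molTargets(ms))
  Xm <- fpMatrix(maccsKeys(ms)); Xe <- fpMatrix(ecfp(ms))
  rss <- function(X) {
    keep <- X[, colMeans(X) > 0 & colMeans(X) < 1, drop = FALSE]
    sum(lm.fit(cbind(1, keep), y)$residuals^2)
  }
  ## omitting either block leaves unexplained residual variance; the
  ## conjoint design explains everything (zero noise)
  rssM <- rss(Xm[, sig$bitsMaccs, drop = FALSE])
  rssE <- rss(Xe[, sig$bitsEcfp, drop = FALSE])
  rssC <- sum(lm.fit(cbind(1, Xm[, sig$bitsMaccs], Xe[, sig$bitsEcfp]),
                     y)$residuals^2)
  expect_lt(rssC, 1e-12)
  expect_gt(rssM, rssC + 1)
  expect_gt(rssE, rssC + 1)
})

test_that("toy complexes exercise the pocket rules by construction", {
  crs <- genComplexes(5, seed = 2)
  expect_length(crs, 5L)
  for (cr in crs) {
    nonSolvent <- cr@proteinAtoms[!cr@proteinAtoms$resname %in%
                                    c("HOH", "ZN"), ]
    keep <- bruteForcePocket(ComplexRecord(cr@id, cr@ligandAtoms, nonSolvent),
                             4.5)
    expect_gte(sum(keep), 1L)          # at least one atom inside 4.5 A
    expect_gte(sum(!keep), 1L)         # and one outside
    expect_equal(sum(cr@proteinAtoms$resname == "HOH"), 2L)
    expect_equal(sum(cr@proteinAtoms$resname == "ZN"), 1L)
    expect_true(all(is.finite(as.matrix(cr@proteinAtoms[, c("x", "y", "z")]))))
  }
  ## determinism
  crs2 <- genComplexes(5, seed = 2)
  expect_equal(crs[[3]]@proteinAtoms$x, crs2[[3]]@proteinAtoms$x)
  expect_false(isTRUE(all.equal(crs[[1]]@proteinAtoms$x,
                                genComplexes(5, seed = 3)[[1]]@proteinAtoms$x)))
})

test_that("the full synthetic pipeline runs without external inputs", {
  cfg <- syntheticConfig(nMolecules = 60L, seed = 19L)
  ms <- genTargets(genMolecules(cfg), cfg)
  fps <- featurize(ms)
  sp <- randomSplit(ms, seed = 1)
  res <- gridSearch(searchSpace("svr", list(cost = c(1, 5))),
                    fpMatrix(fps)[trainIdx(sp), ],
                    unname(molTargets(ms))[trainIdx(sp)],
                    nFolds = 3, seed = 1)
  m <- trainModel(modelSpec("svr", hyperparams = res$bestParams, seed = 1),
                  fpMatrix(fps)[trainIdx(sp), ],
                  unname(molTargets(ms))[trainIdx(sp)])
  rep <- metricsReport(unname(molTargets(ms))[testIdx(sp)],
                       predictTarget(m, fpMatrix(fps)[testIdx(sp), ]))
  expect_true(is.finite(rep$pearson))
  expect_equal(rep$n, length(testIdx(sp)))
})
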