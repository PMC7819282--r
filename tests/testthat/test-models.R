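## Small deterministic design shared by the model contracts: targets are a
## fixed linear function of a few fingerprint bits.
.linearDesign <- function(n = 120L, seed = 2L, noiseSd = 0) {
  fx <- testFeatures(n = n, seed = seed, noiseSd = noiseSd)
  list(X = fpMatrix(fx$fps), y = fx$y)
}

test_that("every family recovers a constant target on its training rows", {
  set.seed(1)
  X <- matrix(rbinom(40 * 30, 1, 0.3), 40, 30)
  y <- rep(1.7, 40)
  tolerances <- c(rf = 1e-8, svr = 0.15, xgb = 0.05, dnn = 0.2, lstm = 0.2)
  for (fam in c("rf", "svr", "xgb", "dnn", "lstm")) {
    hp <- switch(fam, dnn = list(width = 10L, epochs = 50L),
                 lstm = list(units1 = 8L, units2 = 8L, epochs = 50L), list())
    ## suppressWarnings: tree libraries warn about few unique responses
    m <- suppressWarnings(
      trainModel(modelSpec(fam, hyperparams = hp, seed = 1), X, y))
    p <- predictTarget(m, X)
    expect_lt(max(abs(p - 1.7)), tolerances[[fam]], label = fam)
  }
})

test_that("flexible families drive training error below the noise floor on planted signal", {
  d <- .linearDesign(n = 120L, noiseSd = 0)   # noiseless linear design
  for (fam in c("rf", "xgb", "dnn")) {
    hp <- if (fam == "dnn") list(epochs = 150L, dropout = 0) else list()
    m <- suppressWarnings(
      trainModel(modelSpec(fam, hyperparams = hp, seed = 3), d$X, d$y))
    trainRmse <- rmse(d$y, predictTarget(m, d$X))
    ## well below the 0.5 noise sd the generator would otherwise add
    expect_lt(trainRmse, 0.25, label = fam)
  }
})

test_that("training is reproducible under a fixed seed", {
  d <- .linearDesign(n = 60L, noiseSd = 0.5)
  Xnew <- d$X[1:20, ]
  for (fam in c("rf", "svr", "xgb")) {
    m1 <- trainModel(modelSpec(fam, seed = 11), d$X, d$y)
    m2 <- trainModel(modelSpec(fam, seed = 11), d$X, d$y)
    expect_identical(predictTarget(m1, Xnew), predictTarget(m2, Xnew),
                     info = fam)
  }
  for (fam in c("dnn", "lstm")) {
    hp <- if (fam == "dnn") list(width = 16L, epochs = 20L)
          else list(units1 = 8L, units2 = 8L, epochs = 20L)
    m1 <- trainModel(modelSpec(fam, hyperparams = hp, seed = 11), d$X, d$y)
    m2 <- trainModel(modelSpec(fam, hyperparams = hp, seed = 11), d$X, d$y)
    expect_equal(predictTarget(m1, Xnew), predictTarget(m2, Xnew),
                 tolerance = 1e-5, info = fam)
  }
})

test_that("prediction contracts: shapes, duplicates, mismatches", {
  d <- .linearDesign(n = 60L)
  m <- trainModel(modelSpec("svr", seed = 1), d$X, d$y)
  ## empty input gives an empty prediction vector
  expect_length(predictTarget(m, d$X[0, , drop = FALSE]), 0L)
  ## duplicated rows predict identically
  p <- predictTarget(m, d$X[c(1, 1, 2), ])
  expect_identical(p[1], p[2])
  ## width mismatch is an error
  expect_error(predictTarget(m, d$X[, 1:100]), "columns")
  ## training-input mismatches are errors
  expect_error(trainModel(modelSpec("svr"), d$X, d$y[-1]), "row count")
  expect_error(trainModel(modelSpec("svr"), d$X, c(d$y[-1], NA)), "finite")
})

test_that("model specs validate hyperparameter names", {
  expect_error(modelSpec("svr", hyperparams = list(bogus = 1)), "unknown")
  expect_error(modelSpec("nope"), "arg")
  expect_equal(modelSpec("svr")@hyperparams$cost, 5)
  expect_equal(modelSpec("svr")@hyperparams$gamma, 0.015)
})

test_that("DNN architecture follows its hyperparameters", {
  arch <- buildDnn(2214L, list(width = 100L, activation = "relu"))
  expect_equal(arch$layers$width[arch$layers$layer == "hidden"], 100L)
  expect_error(buildDnn(10L, list(activation = "bogus")), "activation")
  expect_error(buildDnn(10L, list(dropout = 0.9)), "dropout")
  ## dropout 0 gives exactly repeatable forward passes on fixed weights
  d <- .linearDesign(n = 40L)
  m <- trainModel(modelSpec("dnn", hyperparams = list(width = 8L, epochs = 5L,
                                                      dropout = 0),
                            seed = 5), d$X, d$y)
  expect_identical(predictTarget(m, d$X), predictTarget(m, d$X))
})

test_that("LSTM stacks two recurrent layers, a dense layer and a scalar output", {
  arch <- buildLstm(2214L)
  expect_equal(nrow(arch$layers), 4L)
  expect_equal(arch$layers$layer, c("lstm1", "lstm2", "dense", "output"))
  ## first LSTM layer output width defaults to the input width
  expect_equal(arch$layers$width[1], 2214L)
  ## a forward pass returns one scalar per row
  X <- matrix(rbinom(3 * 12, 1, 0.5), 3, 12)
  m <- trainModel(modelSpec("lstm",
                            hyperparams = list(units1 = 6L, units2 = 4L,
                                               denseWidth = 4L, epochs = 2L),
                            seed = 1), X, c(0.1, 0.5, 0.9))
  expect_length(predictTarget(m, X), 3L)
})

test_that("neural loss history has one entry per epoch and decreases on signal", {
  d <- .linearDesign(n = 80L)
  m <- trainModel(modelSpec("dnn", hyperparams = list(epochs = 30L),
                            seed = 2), d$X, d$y,
                  Xval = d$X[1:20, ], yval = d$y[1:20])
  lh <- lossHistory(m)
  expect_equal(nrow(lh), 30L)
  expect_equal(lh$epoch, 1:30)
  expect_true(all(is.finite(lh$train)))
  expect_true(all(is.finite(lh$val)))
  ## learning happened: final training loss is below the initial one
  expect_lt(lh$train[30], lh$train[1])
  ## the running minimum is non-increasing by construction of training
  expect_true(all(diff(cummin(lh$train)) <= 0))
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLossHistory(m, tmp)
  expect_equal(nrow(read.csv(tmp)), 30L)
})

test_that("consensus predictions are the exact element-wise member mean", {
  fx <- testFeatures(n = 60L)
  lay <- fpLayout(fx$fps)
  Xm <- fpMatrix(fx$fps)[, lay$start[1]:lay$end[1]]
  Xe <- fpMatrix(fx$fps)[, lay$start[2]:lay$end[2]]
  ma <- trainModel(modelSpec("svr", "maccs", seed = 1), Xm, fx$y)
  mb <- trainModel(modelSpec("svr", "ecfp", seed = 1), Xe, fx$y)
  cm <- consensusModel(ma, mb)
  p <- consensusPredict(cm, Xm, Xe)
  ## brute-force (a + b) / 2 on every element
  pa <- predictTarget(ma, Xm); pb <- predictTarget(mb, Xe)
  expect_identical(p, (pa + pb) / 2)
  ## identical members collapse to the single model
  cSame <- consensusModel(ma, ma)
  expect_identical(consensusPredict(cSame, Xm, Xm), predictTarget(ma, Xm))
  ## arithmetic-mean sanity and row alignment contract
  expect_error(consensusPredict(cm, Xm[1:3, ], Xe[1:4, ]), "row count")
  mixed <- consensusModel(ma, trainModel(modelSpec("svr", seed = 2), Xe, fx$y))
  expect_s4_class(mixed, "ConsensusModel")
  expect_error(consensusModel(ma, trainModel(modelSpec("rf", seed = 1,
    hyperparams = list(ntree = 10L)), Xe, fx$y)), "same model family")
})
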