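#' @include AllClasses.R AllGenerics.R nn.R splitters.R
NULL

#' Default hyperparameters per model family
#'
#' Returns the full named list of tunable hyperparameters for a family with
#' the package defaults. SVR defaults are the RBF kernel with C = 5 and
#' gamma = 0.015. RF/XGB/DNN/LSTM defaults are documented package choices
#' exposed for tuning (see \code{\link{searchSpace}}); the DNN uses the Adam
#' optimizer at learning rate 0.001.
#'
#' @param family one of \code{"rf"}, \code{"svr"}, \code{"xgb"},
#'   \code{"lstm"}, \code{"dnn"}.
#' @return Named list of hyperparameter defaults.
#' @export
defaultHyperparams <- function(family) {
  switch(match.arg(family, .MODEL_FAMILIES),
    rf = list(ntree = 300L, mtry = NA, nodesize = 5L),
    svr = list(kernel = "radial", cost = 5, gamma = 0.015, epsilon = 0.1),
    xgb = list(nrounds = 200L, maxDepth = 6L, eta = 0.1, subsample = 1,
               nthread = 1L),
    dnn = list(width = 100L, activation = "relu", dropout = 0.1,
               epochs = 100L, batchSize = 32L, lr = 0.001),
    lstm = list(units1 = NA, units2 = 64L, denseWidth = 32L, epochs = 60L,
                batchSize = 32L, lr = 0.001))
}

#' Construct a ModelSpec
#'
#' @param family regressor family: rf, svr, xgb, lstm or dnn.
#' @param representation fingerprint representation the model consumes.
#' @param hyperparams named list overriding \code{\link{defaultHyperparams}};
#'   unknown names are rejected.
#' @param seed integer seed driving all stochastic elements of training.
#' @return A \linkS4class{ModelSpec}.
#' @examples
#' modelSpec("svr", "conjoint")
#' @export
modelSpec <- function(family, representation = "conjoint",
                      hyperparams = list(), seed = 1L) {
  family <- match.arg(family, .MODEL_FAMILIES)
  hp <- utils::modifyList(defaultHyperparams(family), hyperparams)
  new("ModelSpec", family = family, representation = representation,
      hyperparams = hp, seed = as.integer(seed))
}

## ---- architecture builders ----------------------------------------------

#' Build an untrained feed-forward (DNN) regression network
#'
#' Input layer, one fully connected hidden layer with the chosen activation
#' and (inverted) dropout, and a scalar linear output; trained with Adam at
#' learning rate 0.001.
#'
#' @param inputLen feature-vector width.
#' @param hyperparams named list (width, activation, dropout, epochs,
#'   batchSize, lr); missing entries take the dnn defaults.
#' @return A list describing the untrained network (family, layer table,
#'   initial parameters are created at fit time).
#' @export
buildDnn <- function(inputLen, hyperparams = list()) {
  hp <- utils::modifyList(defaultHyperparams("dnn"), hyperparams)
  if (!hp$activation %in% names(.ACTIVATIONS))
    stop("invalid activation: ", hp$activation, " (choose from ",
         paste(names(.ACTIVATIONS), collapse = ", "), ")")
  if (hp$dropout < 0 || hp$dropout > 0.6)
    stop("dropout must lie in [0, 0.6]")
  list(family = "dnn", inputLen = as.integer(inputLen), hyperparams = hp,
       layers = data.frame(
         layer = c("hidden", "output"),
         width = c(as.integer(hp$width), 1L),
         activation = c(hp$activation, "linear")))
}

#' Build an untrained LSTM regression network
#'
#' The input vector is treated as a single time step; two LSTM layers are
#' connected sequentially with one dense layer and one scalar output layer.
#' The output dimension of the first LSTM layer equals the input dimension
#' unless overridden.
#'
#' @param inputLen feature-vector width.
#' @param hyperparams named list (units1, units2, denseWidth, epochs,
#'   batchSize, lr); \code{units1 = NA} means "same as inputLen".
#' @return A list describing the untrained network.
#' @export
buildLstm <- function(inputLen, hyperparams = list()) {
  hp <- utils::modifyList(defaultHyperparams("lstm"), hyperparams)
  if (is.na(hp$units1)) hp$units1 <- as.integer(inputLen)
  list(family = "lstm", inputLen = as.integer(inputLen), hyperparams = hp,
       layers = data.frame(
         layer = c("lstm1", "lstm2", "dense", "output"),
         width = as.integer(c(hp$units1, hp$units2, hp$denseWidth, 1L)),
         activation = c("lstm", "lstm", "relu", "linear")))
}

## ---- training -----------------------------------------------------------

.asFpMatrix <- function(X) {
  if (is(X, "FingerprintSet")) fpMatrix(X) else as.matrix(X)
}

#' Train a regressor on a fingerprint matrix
#'
#' Fits the family named in \code{spec} to (X, y). All stochastic elements
#' (bagging, minibatch order, weight initialization, dropout) are driven by
#' \code{spec@seed}; tree and kernel families are bitwise reproducible and
#' the neural families reproduce to floating tolerance. Neural families
#' record a per-epoch (train, validation) MSE loss history. The neural
#' families fit the target mean as a fixed offset and train on centered
#' targets (losses are reported on that centered scale).
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param X fingerprint matrix or \linkS4class{FingerprintSet} (rows =
#'   records).
#' @param y numeric target vector, one finite value per row of X.
#' @param Xval,yval optional validation data for the neural loss history.
#' @note A constant target vector is a degenerate corner for epsilon-SVR
#'   (no support vectors); it is fitted as the exact constant predictor.
#' @return A \linkS4class{TrainedModel}.
#' @export
trainModel <- function(spec, X, y, Xval = NULL, yval = NULL) {
  stopifnot(is(spec, "ModelSpec"))
  X <- .asFpMatrix(X)
  if (nrow(X) != length(y))
    stop("X row count (", nrow(X), ") must equal y length (", length(y), ")")
  if (!all(is.finite(y))) stop("targets must be finite")
  if (!is.null(Xval)) Xval <- .asFpMatrix(Xval)
  hp <- spec@hyperparams
  hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  fit <- switch(spec@family,
    rf = .withSeed(spec@seed, {
      mtry <- if (is.na(hp$mtry)) max(1L, floor(ncol(X) / 3)) else hp$mtry
      randomForest::randomForest(x = X, y = y, ntree = hp$ntree, mtry = mtry,
                                 nodesize = hp$nodesize)
    }),
    svr = if (stats::sd(y) == 0) list(constant = y[1])
          else e1071::svm(x = X, y = y, type = "eps-regression",
                          kernel = hp$kernel, cost = hp$cost, gamma = hp$gamma,
                          epsilon = hp$epsilon, scale = FALSE),
    xgb = .withSeed(spec@seed,
      xgboost::xgb.train(params = list(max_depth = hp$maxDepth, eta = hp$eta,
                                       subsample = hp$subsample,
                                       nthread = hp$nthread,
                                       objective = "reg:squarederror"),
                         data = xgboost::xgb.DMatrix(X, label = y,
                                                     nthread = hp$nthread),
                         nrounds = hp$nrounds, verbose = 0)),
    dnn = .withSeed(spec@seed, {
      arch <- buildDnn(ncol(X), hp)
      yMean <- mean(y)
      params <- .dnnInit(ncol(X), arch$hyperparams$width)
      drp <- arch$hyperparams$dropout
      fwd <- function(p, Xb, train = FALSE) {
        mask <- if (train && drp > 0)
          matrix(stats::rbinom(nrow(Xb) * arch$hyperparams$width, 1, 1 - drp),
                 nrow(Xb)) / (1 - drp)
        fw <- .dnnForward(p, Xb, arch$hyperparams$activation, mask)
        fw$dropMask <- mask
        fw
      }
      grd <- function(p, Xb, yb, fw)
        .dnnGrads(p, Xb, yb, fw, arch$hyperparams$activation, fw$dropMask)
      tr <- .nnTrain(params, X, y - yMean, fwd, grd,
                     epochs = arch$hyperparams$epochs,
                     batchSize = arch$hyperparams$batchSize,
                     lr = arch$hyperparams$lr, Xval = Xval,
                     yval = if (is.null(yval)) NULL else yval - yMean)
      hist <- tr$lossHistory
      list(arch = arch, params = tr$params, yMean = yMean)
    }),
    lstm = .withSeed(spec@seed, {
      arch <- buildLstm(ncol(X), hp)
      h <- arch$hyperparams
      yMean <- mean(y)
      params <- .lstmInit(ncol(X), h$units1, h$units2, h$denseWidth)
      fwd <- function(p, Xb, train = FALSE) .lstmForward(p, Xb)
      grd <- function(p, Xb, yb, fw) .lstmGrads(p, Xb, yb, fw)
      tr <- .nnTrain(params, X, y - yMean, fwd, grd, epochs = h$epochs,
                     batchSize = h$batchSize, lr = h$lr,
                     Xval = Xval, yval = if (is.null(yval)) NULL
                                         else yval - yMean)
      hist <- tr$lossHistory
      list(arch = arch, params = tr$params, yMean = yMean)
    }))
  new("TrainedModel", spec = spec, fit = fit, lossHistory = hist,
      inputLen = ncol(X))
}

#' @describeIn predictTarget predict from a fitted regressor; errors when the
#'   matrix width does not match the fitted representation length.
setMethod("predictTarget", "TrainedModel", function(object, X) {
  X <- .asFpMatrix(X)
  if (ncol(X) != object@inputLen)
    stop("X has ", ncol(X), " columns but the model was fitted on ",
         object@inputLen)
  if (nrow(X) == 0L) return(numeric(0))
  switch(object@spec@family,
    rf = unname(stats::predict(object@fit, X)),
    svr = if (is.list(object@fit) && !is.null(object@fit$constant))
            rep(object@fit$constant, nrow(X))
          else unname(stats::predict(object@fit, X)),
    xgb = unname(stats::predict(object@fit,
                                xgboost::xgb.DMatrix(X, nthread = 1L))),
    dnn = unname(.dnnForward(object@fit$params, X,
                             object@fit$arch$hyperparams$activation)$yhat) +
          object@fit$yMean,
    lstm = unname(.lstmForward(object@fit$params, X)$yhat) +
           object@fit$yMean)
})

## ---- consensus ensemble -------------------------------------------------

#' Construct a consensus model from two standalone-fingerprint members
#'
#' @param memberA \linkS4class{TrainedModel} trained on the MACCS
#'   representation.
#' @param memberB \linkS4class{TrainedModel} trained on the ECFP
#'   representation; must share \code{memberA}'s family.
#' @return A \linkS4class{ConsensusModel}.
#' @export
consensusModel <- function(memberA, memberB) {
  new("ConsensusModel", memberA = memberA, memberB = memberB)
}

#' Consensus prediction: unweighted mean of the two members
#'
#' @param cm a \linkS4class{ConsensusModel}.
#' @param Xmaccs MACCS fingerprint matrix for the records to predict.
#' @param Xecfp ECFP fingerprint matrix for the same records, aligned by row.
#' @return Numeric vector: element-wise \code{(predA + predB) / 2}.
#' @export
consensusPredict <- function(cm, Xmaccs, Xecfp) {
  Xmaccs <- .asFpMatrix(Xmaccs); Xecfp <- .asFpMatrix(Xecfp)
  if (nrow(Xmaccs) != nrow(Xecfp))
    stop("member inputs must have the same row count")
  (predictTarget(cm@memberA, Xmaccs) + predictTarget(cm@memberB, Xecfp)) / 2
}

## ---- persistence --------------------------------------------------------

#' Export a neural loss history as CSV
#'
#' One row per epoch with the training and validation MSE, suitable for
#' loss-curve plots.
#'
#' @param model a \linkS4class{TrainedModel} of a neural family.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeLossHistory <- function(model, path) {
  utils::write.csv(lossHistory(model), path, row.names = FALSE)
  invisible(path)
}
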