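#' @include AllClasses.R
NULL

## Minimal neural-network engine used by the dnn and lstm model families:
## dense feed-forward and single-timestep LSTM regression heads trained by
## minibatch Adam on the mean-squared-error loss. Written directly in R
## matrix algebra; single-threaded and fully seeded, so repeated runs with
## the same seed agree to floating tolerance.

.ACTIVATIONS <- list(
  relu = list(f = function(x) pmax(x, 0),
              df = function(x, a) (x > 0) * 1),
  tanh = list(f = tanh,
              df = function(x, a) 1 - a^2),
  linear = list(f = identity,
                df = function(x, a) matrix(1, nrow(x), ncol(x))),
  softsign = list(f = function(x) x / (1 + abs(x)),
                  df = function(x, a) 1 / (1 + abs(x))^2)
)

.sigmoid <- function(x) 1 / (1 + exp(-x))

## Glorot-uniform initial weights.
.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, st, lr = 0.001, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(params)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

## ---- dense feed-forward network -----------------------------------------

.dnnInit <- function(d, width) {
  ## the output layer starts at zero so an untrained network predicts the
  ## target mean (the targets are centered by the caller)
  list(W1 = .glorot(d, width), b1 = matrix(0, 1, width),
       W2 = matrix(0, width, 1), b2 = matrix(0, 1, 1))
}

.dnnForward <- function(p, X, activation, dropMask = NULL) {
  act <- .ACTIVATIONS[[activation]]
  z1 <- X %*% p$W1 + matrix(p$b1, nrow(X), ncol(p$W1), byrow = TRUE)
  a1 <- act$f(z1)
  if (!is.null(dropMask)) a1 <- a1 * dropMask
  yhat <- drop(a1 %*% p$W2) + p$b2[1]
  list(z1 = z1, a1 = a1, yhat = yhat)
}

.dnnGrads <- function(p, X, y, fw, activation, dropMask = NULL) {
  n <- nrow(X)
  act <- .ACTIVATIONS[[activation]]
  dy <- matrix(2 * (fw$yhat - y) / n, n, 1)
  da1 <- tcrossprod(dy, p$W2)
  if (!is.null(dropMask)) da1 <- da1 * dropMask
  dz1 <- da1 * act$df(fw$z1, fw$a1)
  list(W1 = crossprod(X, dz1), b1 = matrix(colSums(dz1), 1),
       W2 = crossprod(fw$a1, dy), b2 = matrix(sum(dy), 1, 1))
}

## ---- single-timestep LSTM stack -----------------------------------------

.lstmLayerInit <- function(d, u) {
  list(W = .glorot(d, 4L * u), b = matrix(0, 1, 4L * u))
}

## One LSTM cell evaluation at time step 1 (zero initial hidden/cell state;
## the forget gate is present but acts on the zero initial cell state).
.lstmLayerForward <- function(lp, X) {
  u <- ncol(lp$W) %/% 4L
  z <- X %*% lp$W + matrix(lp$b, nrow(X), 4L * u, byrow = TRUE)
  i <- .sigmoid(z[, 1:u, drop = FALSE])
  g <- tanh(z[, (2L * u + 1L):(3L * u), drop = FALSE])
  o <- .sigmoid(z[, (3L * u + 1L):(4L * u), drop = FALSE])
  cc <- i * g
  hc <- tanh(cc)
  list(i = i, g = g, o = o, cc = cc, hc = hc, h = o * hc)
}

.lstmLayerBackward <- function(lp, X, fw, dh) {
  u <- ncol(lp$W) %/% 4L
  do <- dh * fw$hc
  dzo <- do * fw$o * (1 - fw$o)
  dc <- dh * fw$o * (1 - fw$hc^2)
  dzi <- dc * fw$g * fw$i * (1 - fw$i)
  dzg <- dc * fw$i * (1 - fw$g^2)
  dz <- cbind(dzi, dzi * 0, dzg, dzo)
  list(W = crossprod(X, dz), b = matrix(colSums(dz), 1),
       dX = tcrossprod(dz, lp$W))
}

.lstmInit <- function(d, units1, units2, denseWidth) {
  c(setNames(.lstmLayerInit(d, units1), c("W_l1", "b_l1")),
    setNames(.lstmLayerInit(units1, units2), c("W_l2", "b_l2")),
    list(Wd = .glorot(units2, denseWidth), bd = matrix(0, 1, denseWidth),
         Wo = matrix(0, denseWidth, 1), bo = matrix(0, 1, 1)))
}

.lstmForward <- function(p, X) {
  l1 <- .lstmLayerForward(list(W = p$W_l1, b = p$b_l1), X)
  l2 <- .lstmLayerForward(list(W = p$W_l2, b = p$b_l2), l1$h)
  zd <- l2$h %*% p$Wd + matrix(p$bd, nrow(X), ncol(p$Wd), byrow = TRUE)
  ad <- pmax(zd, 0)
  yhat <- drop(ad %*% p$Wo) + p$bo[1]
  list(l1 = l1, l2 = l2, zd = zd, ad = ad, yhat = yhat)
}

.lstmGrads <- function(p, X, y, fw) {
  n <- nrow(X)
  dy <- matrix(2 * (fw$yhat - y) / n, n, 1)
  dWo <- t(fw$ad) %*% dy
  dad <- dy %*% t(p$Wo)
  dzd <- dad * (fw$zd > 0)
  dWd <- t(fw$l2$h) %*% dzd
  dh2 <- dzd %*% t(p$Wd)
  b2 <- .lstmLayerBackward(list(W = p$W_l2, b = p$b_l2), fw$l1$h, fw$l2, dh2)
  b1 <- .lstmLayerBackward(list(W = p$W_l1, b = p$b_l1), X, fw$l1, b2$dX)
  list(W_l1 = b1$W, b_l1 = b1$b, W_l2 = b2$W, b_l2 = b2$b,
       Wd = dWd, bd = matrix(colSums(dzd), 1), Wo = dWo,
       bo = matrix(sum(dy), 1, 1))
}

## ---- shared training loop -----------------------------------------------

## Train by minibatch Adam. forward(params, Xb, train=) must return a list
## with $yhat; grads(params, Xb, yb, fw) the gradient list. Returns params
## and a per-epoch data.frame(epoch, train, val): the training loss is the
## running mean of the minibatch MSEs seen during the epoch (the usual
## epoch-loss bookkeeping of deep-learning frameworks); the validation loss
## is a full pass over (Xval, yval) when supplied.
.nnTrain <- function(params, X, y, forward, grads, epochs, batchSize, lr,
                     Xval = NULL, yval = NULL) {
  st <- .adamInit(params)
  n <- nrow(X)
  trLoss <- vaLoss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    bl <- 0
    for (b in split(ord, ceiling(seq_along(ord) / batchSize))) {
      fw <- forward(params, X[b, , drop = FALSE], train = TRUE)
      gr <- grads(params, X[b, , drop = FALSE], y[b], fw)
      up <- .adamStep(params, gr, st, lr = lr)
      params <- up$params; st <- up$state
      bl <- bl + sum((fw$yhat - y[b])^2)
    }
    trLoss[ep] <- bl / n
    vaLoss[ep] <- if (is.null(Xval) || nrow(Xval) == 0L) NA_real_
                  else mean((forward(params, Xval, train = FALSE)$yhat - yval)^2)
  }
  list(params = params,
       lossHistory = data.frame(epoch = seq_len(epochs), train = trLoss,
                                val = vaLoss))
}
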