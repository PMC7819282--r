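#' @include AllClasses.R
NULL

.checkPred <- function(yTrue, yPred, minN = 1L) {
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  if (length(yTrue) < minN) stop("need at least ", minN, " predictions")
  invisible(NULL)
}

#' Mean squared error
#'
#' \code{sum((yTrue - yPred)^2) / n}.
#'
#' @param yTrue observed property values (e.g. experimental logP).
#' @param yPred predicted values, aligned with \code{yTrue}.
#' @return numeric(1).
#' @export
mse <- function(yTrue, yPred) {
  .checkPred(yTrue, yPred)
  sum((yTrue - yPred)^2) / length(yTrue)
}

#' Root mean squared error
#'
#' \code{sqrt(mse(yTrue, yPred))}, in the property's units.
#'
#' @inheritParams mse
#' @return numeric(1).
#' @export
rmse <- function(yTrue, yPred) sqrt(mse(yTrue, yPred))

#' Pearson correlation between observed and predicted values
#'
#' Computes \deqn{\frac{\sum (a - \bar a)(b - \bar b)}
#'   {\sqrt{\sum (a - \bar a)^2 \sum (b - \bar b)^2}}}
#' exactly. A constant input vector leaves the coefficient undefined and is
#' an error, never a silent zero. Note this is the (unsquared) correlation
#' coefficient r; use \code{\link{pearsonR2}} for its square.
#'
#' @inheritParams mse
#' @return numeric(1) in [-1, 1].
#' @export
pearsonR <- function(yTrue, yPred) {
  .checkPred(yTrue, yPred, minN = 2L)
  a <- yTrue - mean(yTrue)
  b <- yPred - mean(yPred)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) stop("Pearson correlation is undefined for a constant vector")
  sum(a * b) / den
}

#' Squared Pearson correlation
#'
#' @inheritParams mse
#' @return numeric(1) in [0, 1].
#' @export
pearsonR2 <- function(yTrue, yPred) pearsonR(yTrue, yPred)^2

#' Deviation bins (Tetko criteria)
#'
#' Classifies each absolute deviation |yTrue - yPred| as
#' \emph{acceptable} (deviation of at most 0.5), \emph{disputable}
#' ((0.5, 1.0]) or \emph{unacceptable} (> 1.0) and returns the three
#' percentages. Boundary convention: exactly 0.5 is acceptable, exactly 1.0
#' is disputable.
#'
#' @inheritParams mse
#' @return Named numeric(3): acceptable, disputable, unacceptable
#'   (percentages summing to 100).
#' @export
deviationBins <- function(yTrue, yPred) {
  .checkPred(yTrue, yPred)
  d <- abs(yTrue - yPred)
  n <- length(d)
  c(acceptable = 100 * sum(d <= 0.5) / n,
    disputable = 100 * sum(d > 0.5 & d <= 1.0) / n,
    unacceptable = 100 * sum(d > 1.0) / n)
}

#' One-trial metrics report
#'
#' Bundles the evaluation metrics for one prediction set into a one-row
#' data.frame: MSE, RMSE, Pearson r and r-squared, the three deviation-bin
#' percentages and the record count.
#'
#' @inheritParams mse
#' @return A one-row data.frame.
#' @export
metricsReport <- function(yTrue, yPred) {
  bins <- deviationBins(yTrue, yPred)
  data.frame(mse = mse(yTrue, yPred), rmse = rmse(yTrue, yPred),
             pearson = pearsonR(yTrue, yPred),
             pearson2 = pearsonR2(yTrue, yPred),
             acceptable = bins[["acceptable"]],
             disputable = bins[["disputable"]],
             unacceptable = bins[["unacceptable"]],
             n = length(yTrue))
}

#' Aggregate per-trial metric reports
#'
#' Mean and sample standard deviation of each metric across repeated trials
#' (the spread is reported as 0 for a single trial).
#'
#' @param reports a data.frame of stacked \code{\link{metricsReport}} rows,
#'   or a list of such rows.
#' @return A list with \code{perTrial} (the stacked data.frame), \code{mean}
#'   and \code{sd} (named numeric vectors) and \code{nTrials}.
#' @export
aggregateReports <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports))
    reports <- do.call(rbind, reports)
  if (!nrow(reports)) stop("no reports to aggregate")
  cols <- setdiff(names(reports), "n")
  mu <- vapply(reports[cols], mean, numeric(1))
  sdv <- if (nrow(reports) == 1L) setNames(rep(0, length(cols)), cols)
         else vapply(reports[cols], stats::sd, numeric(1))
  list(perTrial = reports, mean = mu, sd = sdv, nTrials = nrow(reports))
}

#' Principal-component projection of a fingerprint matrix
#'
#' Mean-centered PCA; components are ordered by decreasing explained
#' variance. Used to visualize how much chemical space each fingerprint
#' scheme spreads the data over.
#'
#' @param X fingerprint matrix or \linkS4class{FingerprintSet}.
#' @param nComponents number of components to keep (default 2).
#' @return A list with \code{coords} (n x nComponents scores) and
#'   \code{explainedVar} (fraction of total variance per component).
#' @export
pcaProject <- function(X, nComponents = 2L) {
  X <- .asFpMatrix(X)
  if (nComponents > min(dim(X)))
    stop("nComponents must not exceed min(rows, columns)")
  vars <- apply(X, 2, stats::var)
  if (all(vars == 0)) stop("degenerate input: no variance to project")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x[, seq_len(nComponents), drop = FALSE],
       explainedVar = ev[seq_len(nComponents)])
}
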