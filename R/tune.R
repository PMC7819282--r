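#' @include AllClasses.R models.R
NULL

#' Declare a hyperparameter search space
#'
#' A named list of candidate values per hyperparameter for one model family.
#' The default DNN grid covers hidden widths \{10, 20, 40, 50, 60, 100, 300,
#' 500\}, activations \{softsign, relu, linear, tanh\} and dropout 0 to 0.6
#' in steps of 0.1; batch size and epoch count are also searchable.
#'
#' @param family model family the grid applies to.
#' @param grid named list of candidate-value vectors; \code{NULL} gives the
#'   family's default grid.
#' @return A list with elements \code{family} and \code{grid}.
#' @export
searchSpace <- function(family, grid = NULL) {
  family <- match.arg(family, .MODEL_FAMILIES)
  if (is.null(grid)) {
    grid <- switch(family,
      dnn = list(width = c(10L, 20L, 40L, 50L, 60L, 100L, 300L, 500L),
                 activation = c("softsign", "relu", "linear", "tanh"),
                 dropout = seq(0, 0.6, by = 0.1)),
      svr = list(cost = c(1, 5, 10), gamma = c(0.001, 0.015, 0.1)),
      rf = list(ntree = c(100L, 300L, 500L), nodesize = c(1L, 5L, 10L)),
      xgb = list(nrounds = c(100L, 200L), maxDepth = c(4L, 6L, 8L)),
      lstm = list(units2 = c(32L, 64L), denseWidth = c(16L, 32L)))
  }
  bad <- setdiff(names(grid), names(defaultHyperparams(family)))
  if (length(bad)) stop("unknown hyperparameters in grid: ",
                        paste(bad, collapse = ", "))
  if (!length(grid) || any(!lengths(grid))) stop("grid must be non-empty")
  list(family = family, grid = grid)
}

## Rough parameter-count proxy used to break score ties toward the smaller
## model: neural widths, forest/boosting sizes, SVR regularization strength.
.capacityScore <- function(family, params) {
  p <- params
  switch(family,
    dnn = as.numeric(p$width %||% 100),
    lstm = as.numeric((p$units2 %||% 64)) + as.numeric(p$denseWidth %||% 32),
    rf = as.numeric(p$ntree %||% 300),
    xgb = as.numeric(p$nrounds %||% 200) * 2^as.numeric(p$maxDepth %||% 6),
    svr = as.numeric(p$cost %||% 5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grid search with k-fold cross-validation
#'
#' Evaluates every point of the grid's Cartesian product by k-fold
#' cross-validation on the supplied (training) data, scoring each candidate
#' by the mean of per-fold negative mean squared error (higher is better) --
#' the held-out test partition must never be passed in. Candidates that fail
#' to train are scored as worst and logged, and the search continues. Ties
#' are broken toward the smaller model, then by grid order.
#'
#' @param space a \code{\link{searchSpace}}.
#' @param X training fingerprint matrix (or \linkS4class{FingerprintSet}).
#' @param y training targets.
#' @param nFolds number of folds (default 5, minimum 2).
#' @param seed seed for the fold shuffle and candidate fits.
#' @return A list (class \code{searchResult}) with \code{bestParams},
#'   \code{table} (per-candidate mean score, spread and capacity),
#'   \code{nFolds}, \code{folds} and \code{failures}.
#' @export
gridSearch <- function(space, X, y, nFolds = 5L, seed = 1L) {
  stopifnot(nFolds >= 2L)
  X <- .asFpMatrix(X)
  n <- nrow(X)
  stopifnot(n == length(y), n >= nFolds)
  folds <- .withSeed(seed, split(sample.int(n), rep(seq_len(nFolds),
                                                    length.out = n)))
  cand <- expand.grid(space$grid, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  scores <- matrix(NA_real_, nrow(cand), nFolds)
  failures <- character()
  for (ci in seq_len(nrow(cand))) {
    hp <- as.list(cand[ci, , drop = FALSE])
    names(hp) <- names(cand)
    for (fi in seq_len(nFolds)) {
      hold <- folds[[fi]]
      fitTry <- tryCatch({
        m <- trainModel(modelSpec(space$family, hyperparams = hp,
                                  seed = seed + fi),
                        X[-hold, , drop = FALSE], y[-hold])
        pred <- predictTarget(m, X[hold, , drop = FALSE])
        -mean((y[hold] - pred)^2)
      }, error = function(e) conditionMessage(e))
      if (is.character(fitTry)) {
        failures <- c(failures, sprintf("candidate %d fold %d: %s", ci, fi,
                                        fitTry))
        scores[ci, fi] <- -Inf
      } else scores[ci, fi] <- fitTry
    }
  }
  meanScore <- rowMeans(scores)
  capacity <- vapply(seq_len(nrow(cand)), function(ci)
    .capacityScore(space$family, as.list(cand[ci, , drop = FALSE])),
    numeric(1))
  tab <- cbind(cand,
               data.frame(meanScore = meanScore,
                          sdScore = apply(scores, 1, stats::sd),
                          capacity = capacity))
  ord <- order(-meanScore, capacity, seq_len(nrow(cand)))
  best <- ord[1]
  bestParams <- as.list(cand[best, , drop = FALSE])
  names(bestParams) <- names(cand)
  structure(list(bestParams = bestParams, table = tab, nFolds = nFolds,
                 seed = seed, folds = folds, failures = failures),
            class = "searchResult")
}

#' @export
print.searchResult <- function(x, ...) {
  cat(sprintf("Grid search: %d candidates, %d folds, %d failure(s)\n",
              nrow(x$table), x$nFolds, length(x$failures)))
  cat("Best:", paste(names(x$bestParams), unlist(x$bestParams), sep = "=",
                     collapse = ", "), "\n")
  invisible(x)
}

#' Persist a grid-search result (scores table + chosen parameters)
#'
#' Writes \code{<prefix>_scores.csv} with the per-candidate table and
#' \code{<prefix>_best.json} with the selected hyperparameters, so the tuned
#' set can be frozen and reused across datasets.
#'
#' @param res a \code{searchResult} from \code{\link{gridSearch}}.
#' @param prefix output path prefix.
#' @return Written paths, invisibly.
#' @export
writeSearchResult <- function(res, prefix) {
  spath <- paste0(prefix, "_scores.csv")
  bpath <- paste0(prefix, "_best.json")
  utils::write.csv(res$table, spath, row.names = FALSE)
  jsonlite::write_json(list(bestParams = res$bestParams, nFolds = res$nFolds,
                            seed = res$seed,
                            foldSizes = lengths(res$folds)),
                       bpath, auto_unbox = TRUE, digits = NA)
  invisible(c(scores = spath, best = bpath))
}
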