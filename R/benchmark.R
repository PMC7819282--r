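#' @include AllClasses.R models.R evaluate.R splitters.R
NULL

#' Benchmark fingerprint representations across model families
#'
#' Runs the full comparison protocol on one property dataset: featurize once
#' (MACCS, ECFP and their conjoint concatenation), draw \code{nRepeats}
#' random train/validation/test splits, train every requested family on
#' every requested representation, score the held-out test set with
#' \code{\link{metricsReport}}, and aggregate each (family, representation)
#' cell as mean +/- sd across trials. The \code{"consensus"} representation
#' averages the MACCS-member and ECFP-member predictions of the same family
#' and training indices. A family that fails on every repeat is marked
#' failed rather than aborting the run.
#'
#' @param ms a \linkS4class{MoleculeSet} with targets on every record.
#' @param families character subset of rf, svr, xgb, lstm, dnn.
#' @param representations character subset of maccs, ecfp, conjoint,
#'   consensus.
#' @param nRepeats number of repeated trials (default 20).
#' @param baseSeed seed of the first trial; trial i uses baseSeed + i - 1
#'   for both the split and model training.
#' @param spec \linkS4class{FingerprintSpec} for the ECFP block.
#' @param hyperparams named list of per-family hyperparameter overrides,
#'   e.g. \code{list(dnn = list(epochs = 40))} -- the mechanism for freezing
#'   one tuned set and reusing it across datasets.
#' @param testFrac,valRatio split fractions (defaults 0.20 and 4).
#' @return A list with \code{summary} (one row per family x representation
#'   with mean/sd columns), \code{perTrial} (all trial-level reports) and
#'   \code{errors} (character log of failed fits).
#' @export
runBenchmark <- function(ms, families = c("svr", "dnn"),
                         representations = c("maccs", "ecfp", "conjoint",
                                             "consensus"),
                         nRepeats = 20L, baseSeed = 1L,
                         spec = fingerprintSpec(), hyperparams = list(),
                         testFrac = 0.20, valRatio = 4) {
  stopifnot(all(families %in% .MODEL_FAMILIES),
            all(representations %in% .REPRESENTATIONS))
  y <- unname(molTargets(ms))
  if (anyNA(y)) stop("all records must carry a target for benchmarking")
  Xm <- fpMatrix(maccsKeys(ms))
  Xe <- fpMatrix(ecfp(ms, spec))
  Xc <- cbind(Xm, Xe)
  reprX <- list(maccs = Xm, ecfp = Xe, conjoint = Xc)
  splits <- repeatedTrials(ms, nRepeats = nRepeats, baseSeed = baseSeed,
                           testFrac = testFrac, valRatio = valRatio)
  needStandalone <- "consensus" %in% representations
  standalone <- intersect(c("maccs", "ecfp"),
                          union(representations,
                                if (needStandalone) c("maccs", "ecfp")))
  perTrial <- list()
  errors <- character()
  for (r in seq_len(nRepeats)) {
    sp <- splits[[r]]
    tr <- trainIdx(sp); te <- testIdx(sp)
    for (fam in families) {
      seedR <- baseSeed + r - 1L
      hpFam <- hyperparams[[fam]] %||% list()
      fits <- list()
      for (rep in union(setdiff(representations, "consensus"), standalone)) {
        fits[[rep]] <- tryCatch(
          trainModel(modelSpec(fam, rep, hpFam, seed = seedR),
                     reprX[[rep]][tr, , drop = FALSE], y[tr]),
          error = function(e) {
            errors <<- c(errors, sprintf("trial %d %s/%s: %s", r, fam, rep,
                                         conditionMessage(e)))
            NULL
          })
      }
      for (rep in representations) {
        pred <- tryCatch({
          if (rep == "consensus") {
            if (is.null(fits$maccs) || is.null(fits$ecfp))
              stop("consensus members unavailable")
            consensusPredict(consensusModel(fits$maccs, fits$ecfp),
                             Xm[te, , drop = FALSE], Xe[te, , drop = FALSE])
          } else {
            if (is.null(fits[[rep]])) stop("member fit unavailable")
            predictTarget(fits[[rep]], reprX[[rep]][te, , drop = FALSE])
          }
        }, error = function(e) {
          errors <<- c(errors, sprintf("trial %d %s/%s predict: %s", r, fam,
                                       rep, conditionMessage(e)))
          NULL
        })
        if (!is.null(pred)) {
          rep1 <- metricsReport(y[te], pred)
          rep1$trial <- r; rep1$family <- fam; rep1$representation <- rep
          perTrial[[length(perTrial) + 1L]] <- rep1
        }
      }
    }
  }
  perTrial <- do.call(rbind, perTrial)
  cells <- expand.grid(family = families, representation = representations,
                       stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    sub <- perTrial[perTrial$family == cells$family[k] &
                    perTrial$representation == cells$representation[k], ,
                    drop = FALSE]
    if (is.null(sub) || !nrow(sub))
      return(data.frame(family = cells$family[k],
                        representation = cells$representation[k],
                        nTrials = 0L, failed = TRUE,
                        pearson = NA, pearsonSd = NA, rmse = NA, rmseSd = NA,
                        acceptable = NA, disputable = NA, unacceptable = NA))
    agg <- aggregateReports(sub[, c("mse", "rmse", "pearson", "pearson2",
                                    "acceptable", "disputable",
                                    "unacceptable", "n")])
    data.frame(family = cells$family[k],
               representation = cells$representation[k],
               nTrials = nrow(sub), failed = FALSE,
               pearson = agg$mean[["pearson"]], pearsonSd = agg$sd[["pearson"]],
               rmse = agg$mean[["rmse"]], rmseSd = agg$sd[["rmse"]],
               acceptable = agg$mean[["acceptable"]],
               disputable = agg$mean[["disputable"]],
               unacceptable = agg$mean[["unacceptable"]])
  }))
  list(summary = summary, perTrial = perTrial, errors = errors)
}
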