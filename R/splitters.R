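#' @include AllClasses.R AllGenerics.R fingerprints.R
NULL

## Run expr under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.splitN <- function(x) {
  if (is(x, "MoleculeSet")) length(x)
  else if (is.numeric(x) && length(x) == 1L) as.integer(x)
  else stop("expected a MoleculeSet or a record count")
}

#' Random train/validation/test split
#'
#' Uniformly samples \code{round(testFrac * n)} records into the test set,
#' then splits the remainder train:val = \code{valRatio}:1 (validation size
#' = \code{round(remaining / (valRatio + 1))}). The defaults reproduce the
#' 20\% test / 4:1 train:validation protocol, so n = 100 yields
#' \code{|test| = 20}, \code{|train| = 64}, \code{|val| = 16}. Identical
#' (n, seed, fractions) always reproduce the identical split.
#'
#' @param x a \linkS4class{MoleculeSet} or a record count.
#' @param testFrac test fraction in (0, 1); default 0.20.
#' @param valRatio train:validation ratio among non-test records; default 4.
#' @param seed integer seed.
#' @return A \linkS4class{DataSplit}.
#' @export
randomSplit <- function(x, testFrac = 0.20, valRatio = 4, seed = 1L) {
  n <- .splitN(x)
  stopifnot(testFrac > 0, testFrac < 1, valRatio > 0)
  if (n < 5L) stop("need at least 5 records to honor the split fractions")
  .withSeed(seed, {
    test <- sort(sample.int(n, round(testFrac * n)))
    rest <- setdiff(seq_len(n), test)
    val <- sort(sample(rest, round(length(rest) / (valRatio + 1))))
    train <- setdiff(rest, val)
    new("DataSplit", trainIdx = as.integer(train), valIdx = as.integer(val),
        testIdx = as.integer(test), seed = as.integer(seed),
        method = "random")
  })
}

#' Bemis-Murcko scaffold split
#'
#' Groups molecules by Bemis-Murcko scaffold and assigns whole groups,
#' largest first (ties broken by scaffold string), greedily to train until
#' the train quota is reached, then to validation, then to test. No scaffold
#' ever straddles two partitions, so held-out molecules present chemotypes
#' unseen in training. Deterministic; no seed is used.
#'
#' @param ms a \linkS4class{MoleculeSet} with parseable SMILES.
#' @param testFrac test fraction; default 0.20.
#' @param valRatio train:validation ratio among non-test records; default 4
#'   (mirroring the random protocol).
#' @return A \linkS4class{DataSplit} with method \code{"scaffold"}.
#' @export
scaffoldSplit <- function(ms, testFrac = 0.20, valRatio = 4) {
  stopifnot(is(ms, "MoleculeSet"))
  n <- length(ms)
  scaff <- murckoScaffold(ms)
  groups <- split(seq_len(n), scaff)
  sizes <- lengths(groups)
  ord <- order(-sizes, names(groups))
  groups <- groups[ord]
  nTest <- round(testFrac * n)
  nVal <- round((n - nTest) / (valRatio + 1))
  nTrain <- n - nTest - nVal
  train <- integer(); val <- integer(); test <- integer()
  for (g in groups) {
    if (length(train) < nTrain) train <- c(train, g)
    else if (length(val) < nVal) val <- c(val, g)
    else test <- c(test, g)
  }
  new("DataSplit", trainIdx = sort(train), valIdx = sort(val),
      testIdx = sort(test), seed = NA_integer_, method = "scaffold")
}

#' Repeated random splits for trial aggregation
#'
#' Produces \code{nRepeats} independent random splits with seeds
#' \code{baseSeed, baseSeed + 1, ...} so that repeated train/test trials
#' (20 by default, for mean +/- spread reporting) are exactly replayable.
#'
#' @param x a \linkS4class{MoleculeSet} or a record count.
#' @param nRepeats number of trials; default 20.
#' @param baseSeed seed of the first trial.
#' @param testFrac,valRatio forwarded to \code{\link{randomSplit}}.
#' @return A list of \linkS4class{DataSplit}s of length \code{nRepeats}.
#' @export
repeatedTrials <- function(x, nRepeats = 20L, baseSeed = 1L,
                           testFrac = 0.20, valRatio = 4) {
  stopifnot(nRepeats >= 1L)
  lapply(seq_len(nRepeats) - 1L, function(i)
    randomSplit(x, testFrac = testFrac, valRatio = valRatio,
                seed = baseSeed + i))
}

#' Serialize a DataSplit to JSON
#'
#' @param split a \linkS4class{DataSplit}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeSplit <- function(split, path) {
  jsonlite::write_json(
    list(method = split@method,
         seed = if (is.na(split@seed)) NULL else split@seed,
         train = split@trainIdx, val = split@valIdx, test = split@testIdx),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a DataSplit written by \code{writeSplit}
#'
#' @param path JSON path.
#' @return A \linkS4class{DataSplit}.
#' @export
readSplit <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DataSplit", trainIdx = as.integer(j$train), valIdx = as.integer(j$val),
      testIdx = as.integer(j$test),
      seed = if (is.null(j$seed)) NA_integer_ else as.integer(j$seed),
      method = j$method)
}
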