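#' @include AllClasses.R
NULL

#' Accessors for conjointFP classes
#'
#' Small accessor generics in the Bioconductor style: use these instead of
#' reaching into slots.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("molIds", function(x) standardGeneric("molIds"))
#' @rdname accessors
#' @export
setGeneric("molSmiles", function(x) standardGeneric("molSmiles"))
#' @rdname accessors
#' @export
setGeneric("molTargets", function(x) standardGeneric("molTargets"))
#' @rdname accessors
#' @export
setGeneric("propertyName", function(x) standardGeneric("propertyName"))
#' @rdname accessors
#' @export
setGeneric("nFailed", function(x) standardGeneric("nFailed"))
#' @rdname accessors
#' @export
setGeneric("fpMatrix", function(x) standardGeneric("fpMatrix"))
#' @rdname accessors
#' @export
setGeneric("fpScheme", function(x) standardGeneric("fpScheme"))
#' @rdname accessors
#' @export
setGeneric("fpLayout", function(x) standardGeneric("fpLayout"))
#' @rdname accessors
#' @export
setGeneric("fpSource", function(x) standardGeneric("fpSource"))
#' @rdname accessors
#' @export
setGeneric("trainIdx", function(x) standardGeneric("trainIdx"))
#' @rdname accessors
#' @export
setGeneric("valIdx", function(x) standardGeneric("valIdx"))
#' @rdname accessors
#' @export
setGeneric("testIdx", function(x) standardGeneric("testIdx"))
#' @rdname accessors
#' @export
setGeneric("splitMethod", function(x) standardGeneric("splitMethod"))
#' @rdname accessors
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))

#' Predict targets from a fitted model
#'
#' @param object a \linkS4class{TrainedModel}.
#' @param X a fingerprint matrix (or \linkS4class{FingerprintSet}) whose
#'   column count matches the fitted representation width.
#' @return numeric vector, one finite prediction per row (length 0 for an
#'   empty matrix).
#' @export
setGeneric("predictTarget", function(object, X) standardGeneric("predictTarget"))

#' Compute a fingerprint representation
#'
#' Dispatches on the input container and returns a
#' \linkS4class{FingerprintSet} for the scheme in \code{spec}.
#'
#' @param x a \linkS4class{MoleculeSet} or character vector of SMILES.
#' @param spec a \linkS4class{FingerprintSpec}.
#' @param ... passed to methods.
#' @export
setGeneric("featurize", function(x, spec = fingerprintSpec(), ...)
  standardGeneric("featurize"))

## ---- methods: MoleculeSet ----

#' @rdname accessors
setMethod("molIds", "MoleculeSet", function(x) x@ids)
#' @rdname accessors
setMethod("molSmiles", "MoleculeSet", function(x) setNames(x@smiles, x@ids))
#' @rdname accessors
setMethod("molTargets", "MoleculeSet", function(x) setNames(x@target, x@ids))
#' @rdname accessors
setMethod("propertyName", "MoleculeSet", function(x) x@propertyName)
#' @rdname accessors
setMethod("nFailed", "MoleculeSet", function(x) x@nFailed)

#' @describeIn MoleculeSet number of retained molecules
#' @param x a MoleculeSet
#' @export
setMethod("length", "MoleculeSet", function(x) length(x@ids))

#' @describeIn MoleculeSet subset by index or id (drops failed-record log)
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  MoleculeSet(ids = x@ids[i], smiles = x@smiles[i], target = x@target[i],
              propertyName = x@propertyName, metadata = x@metadata)
})

setMethod("show", "MoleculeSet", function(object) {
  cat(sprintf("MoleculeSet of %d molecules (property: %s, %d with values, %d failed at parse)\n",
              length(object@ids), object@propertyName,
              sum(!is.na(object@target)), object@nFailed))
  n <- min(3L, length(object@ids))
  if (n) for (k in seq_len(n))
    cat(sprintf("  %s  %s  %s\n", object@ids[k], object@smiles[k],
                format(object@target[k])))
  if (length(object@ids) > n) cat("  ...\n")
})

## ---- methods: FingerprintSet ----

#' @rdname accessors
setMethod("fpMatrix", "FingerprintSet", function(x) x@bits)
#' @rdname accessors
setMethod("fpScheme", "FingerprintSet", function(x) x@scheme)
#' @rdname accessors
setMethod("fpLayout", "FingerprintSet", function(x) x@layout)
#' @rdname accessors
setMethod("fpSource", "FingerprintSet", function(x) x@source)

#' @describeIn FingerprintSet number of fingerprinted records
#' @param x a FingerprintSet
#' @export
setMethod("length", "FingerprintSet", function(x) nrow(x@bits))

setMethod("show", "FingerprintSet", function(object) {
  cat(sprintf("FingerprintSet: %d x %d bits, scheme=%s, source=%s\n",
              nrow(object@bits), ncol(object@bits), object@scheme,
              object@source))
  cat("  blocks:", paste(sprintf("%s[%d:%d]", object@layout$block,
                                 object@layout$start, object@layout$end),
                         collapse = " "), "\n")
})

## ---- methods: DataSplit ----

#' @rdname accessors
setMethod("trainIdx", "DataSplit", function(x) x@trainIdx)
#' @rdname accessors
setMethod("valIdx", "DataSplit", function(x) x@valIdx)
#' @rdname accessors
setMethod("testIdx", "DataSplit", function(x) x@testIdx)
#' @rdname accessors
setMethod("splitMethod", "DataSplit", function(x) x@method)

setMethod("show", "DataSplit", function(object) {
  cat(sprintf("DataSplit (%s%s): train=%d val=%d test=%d\n", object@method,
              if (is.na(object@seed)) "" else sprintf(", seed=%d", object@seed),
              length(object@trainIdx), length(object@valIdx),
              length(object@testIdx)))
})

## ---- methods: models ----

#' @rdname accessors
setMethod("lossHistory", "TrainedModel", function(x) x@lossHistory)

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: family=%s representation=%s inputLen=%d%s\n",
              object@spec@family, object@spec@representation, object@inputLen,
              if (nrow(object@lossHistory))
                sprintf(" (%d epochs recorded)", nrow(object@lossHistory))
              else ""))
})

setMethod("show", "ConsensusModel", function(object) {
  cat(sprintf("ConsensusModel: family=%s (members: maccs %d bits, ecfp %d bits)\n",
              object@memberA@spec@family, object@memberA@inputLen,
              object@memberB@inputLen))
})

setMethod("show", "ComplexRecord", function(object) {
  cat(sprintf("ComplexRecord %s: %d ligand atoms, %d protein atoms, pKi=%s\n",
              object@id, nrow(object@ligandAtoms), nrow(object@proteinAtoms),
              format(object@target)))
})
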