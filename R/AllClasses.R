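#' @import methods
NULL

.FP_SCHEMES <- c("maccs", "ecfp", "conjoint")
.FP_SOURCES <- c("molecule", "ligand", "pocket", "complex")
.MODEL_FAMILIES <- c("rf", "svr", "xgb", "lstm", "dnn")
.REPRESENTATIONS <- c("maccs", "ecfp", "conjoint", "consensus")

#' FingerprintSpec: parameters of a fingerprint scheme
#'
#' Records which scheme is computed (\code{"maccs"}, \code{"ecfp"} or
#' \code{"conjoint"}) together with the ECFP neighborhood radius (in bond
#' lengths) and folded vector length, and the MACCS key count. Defaults follow
#' common virtual-screening practice: radius-2 ECFP folded to 2048 bits and
#' the 166-key public MACCS dictionary, so a conjoint vector is 166 + 2048 =
#' 2214 bits.
#'
#' @slot scheme character, one of \code{"maccs"}, \code{"ecfp"},
#'   \code{"conjoint"}.
#' @slot ecfpRadius integer neighborhood radius in bond lengths (0--5).
#' @slot ecfpNbits integer folded ECFP length; a power of two up to 4096.
#' @slot maccsNbits integer MACCS key count, fixed at 166.
#' @export
setClass("FingerprintSpec",
  representation(scheme = "character", ecfpRadius = "integer",
                 ecfpNbits = "integer", maccsNbits = "integer"))

setValidity("FingerprintSpec", function(object) {
  msg <- character()
  if (length(object@scheme) != 1L || !object@scheme %in% .FP_SCHEMES)
    msg <- c(msg, sprintf("scheme must be one of %s",
                          paste(.FP_SCHEMES, collapse = ", ")))
  if (length(object@ecfpRadius) != 1L || is.na(object@ecfpRadius) ||
      object@ecfpRadius < 0L || object@ecfpRadius > 5L)
    msg <- c(msg, "ecfpRadius must be an integer in [0, 5]")
  nb <- object@ecfpNbits
  if (length(nb) != 1L || is.na(nb) || nb < 1L || nb > 4096L ||
      bitwAnd(nb, nb - 1L) != 0L)
    msg <- c(msg, "ecfpNbits must be a power of two in [1, 4096]")
  if (length(object@maccsNbits) != 1L || object@maccsNbits != 166L)
    msg <- c(msg, "maccsNbits must be 166 (the public MACCS key dictionary)")
  if (length(msg)) msg else TRUE
})

#' Construct a FingerprintSpec
#'
#' @param scheme fingerprint scheme: \code{"maccs"}, \code{"ecfp"} or
#'   \code{"conjoint"}.
#' @param ecfpRadius ECFP radius in bond lengths (default 2).
#' @param ecfpNbits folded ECFP length, a power of two (default 2048).
#' @return A \linkS4class{FingerprintSpec}.
#' @examples
#' fingerprintSpec("conjoint")
#' @export
fingerprintSpec <- function(scheme = "conjoint", ecfpRadius = 2, ecfpNbits = 2048) {
  new("FingerprintSpec", scheme = scheme, ecfpRadius = as.integer(ecfpRadius),
      ecfpNbits = as.integer(ecfpNbits), maccsNbits = 166L)
}

#' MoleculeSet: molecules with an optional numeric property
#'
#' An ordered collection of molecules, each an identifier plus a SMILES
#' string, optionally annotated with a numeric target property (logP in log
#' units, or pKi). Records whose SMILES failed to parse at read time are not
#' stored here; their count and identities are kept in \code{nFailed} /
#' \code{failed} so that retained + failed always equals the input size.
#' Record order is stable, so integer indices from a \linkS4class{DataSplit}
#' address the same molecules across runs.
#'
#' @slot ids character, unique molecule identifiers.
#' @slot smiles character, one valid SMILES per molecule.
#' @slot target numeric property values (NA where absent).
#' @slot propertyName character(1), e.g. \code{"logP"} or \code{"pKi"}.
#' @slot nFailed integer(1), records dropped at parse time.
#' @slot failed data.frame with columns \code{id}, \code{smiles} for dropped rows.
#' @slot metadata list of free-form provenance (e.g. planted-signal design).
#' @export
setClass("MoleculeSet",
  representation(ids = "character", smiles = "character", target = "numeric",
                 propertyName = "character", nFailed = "integer",
                 failed = "data.frame", metadata = "list"))

setValidity("MoleculeSet", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (length(object@smiles) != n) msg <- c(msg, "ids and smiles lengths differ")
  if (length(object@target) != n) msg <- c(msg, "ids and target lengths differ")
  if (anyDuplicated(object@ids)) msg <- c(msg, "ids must be unique")
  if (length(object@propertyName) != 1L) msg <- c(msg, "propertyName must be length 1")
  if (length(object@nFailed) != 1L || object@nFailed < 0L)
    msg <- c(msg, "nFailed must be a non-negative count")
  if (length(msg)) msg else TRUE
})

#' Construct a MoleculeSet
#'
#' @param ids character identifiers (unique); defaults to \code{M1..Mn}.
#' @param smiles character SMILES strings.
#' @param target numeric property values, NA where absent.
#' @param propertyName name of the property column (default "logP").
#' @param nFailed count of records dropped upstream.
#' @param failed data.frame of dropped records (id, smiles).
#' @param metadata list of provenance entries.
#' @return A \linkS4class{MoleculeSet}.
#' @examples
#' ms <- MoleculeSet(smiles = c("CCO", "c1ccccc1"), target = c(-0.31, 2.13))
#' molSmiles(ms)
#' @export
MoleculeSet <- function(smiles, target = rep(NA_real_, length(smiles)),
                        ids = paste0("M", seq_along(smiles)),
                        propertyName = "logP", nFailed = 0L,
                        failed = data.frame(id = character(), smiles = character()),
                        metadata = list()) {
  new("MoleculeSet", ids = as.character(ids), smiles = as.character(smiles),
      target = as.numeric(target), propertyName = propertyName,
      nFailed = as.integer(nFailed), failed = failed, metadata = metadata)
}

#' ComplexRecord: a protein-ligand complex as typed 3D atom lists
#'
#' Holds the ligand and protein atoms of one complex with Cartesian
#' coordinates in Angstrom. Only element symbol, residue tag and coordinates
#' are retained -- enough for distance-based pocket extraction and
#' perception-based featurization. Waters and monoatomic metal ions are
#' removed from the protein at read time (see \code{\link{readComplex}}).
#'
#' @slot id character(1) complex identifier.
#' @slot ligandAtoms data.frame(element, x, y, z), non-empty.
#' @slot proteinAtoms data.frame(element, resname, x, y, z).
#' @slot target numeric(1) binding affinity (pKi), NA when unknown.
#' @export
setClass("ComplexRecord",
  representation(id = "character", ligandAtoms = "data.frame",
                 proteinAtoms = "data.frame", target = "numeric"))

setValidity("ComplexRecord", function(object) {
  msg <- character()
  la <- object@ligandAtoms; pa <- object@proteinAtoms
  if (nrow(la) == 0L) msg <- c(msg, "ligandAtoms must be non-empty")
  if (!all(c("element", "x", "y", "z") %in% names(la)))
    msg <- c(msg, "ligandAtoms needs columns element, x, y, z")
  if (!all(c("element", "resname", "x", "y", "z") %in% names(pa)))
    msg <- c(msg, "proteinAtoms needs columns element, resname, x, y, z")
  coords <- c(la$x, la$y, la$z, pa$x, pa$y, pa$z)
  if (length(coords) && !all(is.finite(coords)))
    msg <- c(msg, "all coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a ComplexRecord
#'
#' @param id identifier.
#' @param ligandAtoms data.frame(element, x, y, z) in Angstrom.
#' @param proteinAtoms data.frame(element, resname, x, y, z) in Angstrom.
#' @param target pKi value or NA.
#' @return A \linkS4class{ComplexRecord}.
#' @export
ComplexRecord <- function(id, ligandAtoms, proteinAtoms =
                            data.frame(element = character(), resname = character(),
                                       x = numeric(), y = numeric(), z = numeric()),
                          target = NA_real_) {
  new("ComplexRecord", id = as.character(id), ligandAtoms = ligandAtoms,
      proteinAtoms = proteinAtoms, target = as.numeric(target))
}

#' FingerprintSet: a fingerprint matrix with scheme and block layout
#'
#' A dense 0/1 matrix, one row per record, tagged with the scheme that
#' produced it, the provenance of the atoms (whole molecule, ligand, pocket
#' or protein-ligand complex) and a block layout giving, for concatenated
#' schemes, the column range occupied by each component so the standalone
#' vectors are exactly recoverable by slicing.
#'
#' @slot bits integer matrix of 0/1; rownames are record ids.
#' @slot scheme character(1), \code{"maccs"}, \code{"ecfp"} or \code{"conjoint"}.
#' @slot source character(1), one of molecule, ligand, pocket, complex.
#' @slot spec the \linkS4class{FingerprintSpec} used.
#' @slot layout data.frame(block, start, end) column ranges of each block.
#' @export
setClass("FingerprintSet",
  representation(bits = "matrix", scheme = "character", source = "character",
                 spec = "FingerprintSpec", layout = "data.frame"))

setValidity("FingerprintSet", function(object) {
  msg <- character()
  b <- object@bits
  if (!is.numeric(b) && !is.integer(b)) msg <- c(msg, "bits must be numeric")
  else if (length(b) && !all(b %in% c(0L, 1L))) msg <- c(msg, "bits must be 0/1")
  if (!object@scheme %in% .FP_SCHEMES) msg <- c(msg, "invalid scheme")
  if (!object@source %in% .FP_SOURCES) msg <- c(msg, "invalid source")
  lay <- object@layout
  if (!all(c("block", "start", "end") %in% names(lay)))
    msg <- c(msg, "layout needs columns block, start, end")
  else if (nrow(lay) && (lay$start[1] != 1L || any(lay$end < lay$start) ||
           (nrow(lay) > 1 && any(lay$start[-1] != lay$end[-nrow(lay)] + 1L)) ||
           lay$end[nrow(lay)] != ncol(b)))
    msg <- c(msg, "layout blocks must tile 1..ncol(bits) contiguously")
  if (length(msg)) msg else TRUE
})

.fpSet <- function(bits, scheme, source, spec, layout) {
  storage.mode(bits) <- "integer"
  new("FingerprintSet", bits = bits, scheme = scheme, source = source,
      spec = spec, layout = layout)
}

#' DataSplit: disjoint train/validation/test index partition
#'
#' Integer indices into the record order of the dataset that produced it,
#' plus the seed and method, so a split is exactly replayable.
#'
#' @slot trainIdx,valIdx,testIdx integer index vectors, pairwise disjoint.
#' @slot seed integer(1); NA for the deterministic scaffold method.
#' @slot method character(1), \code{"random"} or \code{"scaffold"}.
#' @export
setClass("DataSplit",
  representation(trainIdx = "integer", valIdx = "integer", testIdx = "integer",
                 seed = "integer", method = "character"))

setValidity("DataSplit", function(object) {
  msg <- character()
  all3 <- c(object@trainIdx, object@valIdx, object@testIdx)
  if (anyDuplicated(all3)) msg <- c(msg, "partitions must be pairwise disjoint")
  if (!object@method %in% c("random", "scaffold")) msg <- c(msg, "invalid method")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: regressor family, representation and hyperparameters
#'
#' @slot family character(1): rf, svr, xgb, lstm or dnn.
#' @slot representation character(1): maccs, ecfp, conjoint or consensus.
#' @slot hyperparams named list; names must be valid for the family
#'   (see \code{\link{defaultHyperparams}}).
#' @slot seed integer(1) driving every stochastic element of training.
#' @export
setClass("ModelSpec",
  representation(family = "character", representation = "character",
                 hyperparams = "list", seed = "integer"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@family %in% .MODEL_FAMILIES)
    msg <- c(msg, sprintf("family must be one of %s",
                          paste(.MODEL_FAMILIES, collapse = ", ")))
  if (!object@representation %in% .REPRESENTATIONS)
    msg <- c(msg, "invalid representation")
  if (object@family %in% .MODEL_FAMILIES) {
    bad <- setdiff(names(object@hyperparams),
                   names(defaultHyperparams(object@family)))
    if (length(bad))
      msg <- c(msg, sprintf("unknown hyperparameters for %s: %s",
                            object@family, paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' TrainedModel: a fitted regressor with its spec and loss history
#'
#' @slot spec the \linkS4class{ModelSpec} that produced the fit.
#' @slot fit opaque fitted state (family-specific).
#' @slot lossHistory data.frame(epoch, train, val) for neural families;
#'   zero rows otherwise.
#' @slot inputLen integer(1) fitted feature-vector width.
#' @export
setClass("TrainedModel",
  representation(spec = "ModelSpec", fit = "ANY", lossHistory = "data.frame",
                 inputLen = "integer"))

#' ConsensusModel: two same-family members on the two standalone fingerprints
#'
#' An ensemble that averages (unweighted) the predictions of a
#' MACCS-representation member and an ECFP-representation member of the same
#' regressor family trained on the same records.
#'
#' @slot memberA \linkS4class{TrainedModel} trained on MACCS keys.
#' @slot memberB \linkS4class{TrainedModel} trained on ECFP.
#' @export
setClass("ConsensusModel",
  representation(memberA = "TrainedModel", memberB = "TrainedModel"))

setValidity("ConsensusModel", function(object) {
  if (object@memberA@spec@family != object@memberB@spec@family)
    "consensus members must share the same model family" else TRUE
})
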