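#' @include AllClasses.R AllGenerics.R
NULL

## ---- low-level engine helpers -------------------------------------------

## Evaluate a chemistry-engine call in a short-lived forked child and return
## its result. The engine's fingerprint path retains per-molecule native
## memory for the lifetime of the process; isolating batch calls in a child
## keeps the parent's footprint flat over long benchmark runs. Falls back to
## in-process evaluation where fork is unavailable.
.isolated <- function(f) {
  if (.Platform$OS.type != "unix") return(f())
  job <- parallel::mcparallel(tryCatch(f(), error = function(e)
    structure(list(message = conditionMessage(e)), class = "cfpChildError")))
  res <- parallel::mccollect(job)[[1]]
  if (inherits(res, "cfpChildError")) stop(res$message)
  if (is.null(res)) stop("chemistry engine child process failed")
  res
}

## Batch-convert SMILES to an SDFset (heavy-atom graphs, implicit hydrogens).
.toSdfSet <- function(smiles, ids = paste0("M", seq_along(smiles))) {
  ChemmineR::smiles2sdf(setNames(smiles, ids))
}

## Fingerprint a batch of (pre-validated) SMILES as one input stream; one
## row per molecule.
.fpEngineMatrix <- function(smiles, fpName) {
  .isolated(function() {
    rows <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                   function(m)
                                     ChemmineOB::fingerprint_OB(list(m), fpName))
    do.call(rbind, rows)
  })
}

## 166-key MACCS matrix. OpenBabel fills a 256-bit container; positions
## 1..166 carry the public key dictionary (verified bit-for-bit against an
## independent MACCS implementation on a reference panel).
.maccsMatrix <- function(smiles) {
  .fpEngineMatrix(smiles, "MACCS")[, 1:166, drop = FALSE]
}

## Unfolded (4096-bit) circular fingerprint at the given bond radius.
.ecfpRawMatrix <- function(smiles, radius) {
  .fpEngineMatrix(smiles, paste0("ECFP", 2L * radius))
}

## Fold a bit matrix to nbits columns by OR-ing the two halves repeatedly.
.foldBits <- function(m, nbits) {
  while (ncol(m) > nbits) {
    h <- ncol(m) %/% 2L
    m <- (m[, 1:h, drop = FALSE] | m[, (h + 1):ncol(m), drop = FALSE]) * 1L
  }
  m
}

.oneBlockLayout <- function(block, n) data.frame(block = block, start = 1L,
                                                 end = as.integer(n))

## ---- molecule fingerprints ----------------------------------------------

#' MACCS substructure keys (166 bits)
#'
#' Each of the 166 predefined substructure patterns sets one bit when it
#' matches the molecule. The result is invariant to input atom order and to
#' explicit-hydrogen spelling because matching runs on the perceived
#' heavy-atom graph.
#'
#' @param x a \linkS4class{MoleculeSet} or character vector of valid SMILES.
#' @return A \linkS4class{FingerprintSet} with a 166-column 0/1 matrix.
#' @examples
#' fpMatrix(maccsKeys("c1ccccc1"))[, 160:166]
#' @export
maccsKeys <- function(x) {
  ms <- .asMoleculeSet(x)
  m <- .maccsMatrix(ms@smiles)
  rownames(m) <- ms@ids
  .fpSet(m, "maccs", "molecule", fingerprintSpec("maccs"),
         .oneBlockLayout("maccs", 166L))
}

#' Extended-connectivity fingerprint (ECFP)
#'
#' Circular atom neighborhoods up to \code{ecfpRadius} bond lengths are
#' hashed to integer identifiers and folded into a fixed-width bit vector
#' (presence/absence, not counts). Radius 2 folded to 2048 bits is the
#' default. Folding only ORs bits together, so the radius-0 bits of a
#' molecule remain a subset of its radius-2 bits.
#'
#' @param x a \linkS4class{MoleculeSet} or character vector of valid SMILES.
#' @param spec a \linkS4class{FingerprintSpec}; its \code{ecfpRadius} and
#'   \code{ecfpNbits} are honored.
#' @return A \linkS4class{FingerprintSet} with an \code{ecfpNbits}-column
#'   0/1 matrix.
#' @examples
#' length(fpMatrix(ecfp("CCO"))[1, ])
#' @export
ecfp <- function(x, spec = fingerprintSpec("ecfp")) {
  ms <- .asMoleculeSet(x)
  m <- .foldBits(.ecfpRawMatrix(ms@smiles, spec@ecfpRadius), spec@ecfpNbits)
  rownames(m) <- ms@ids
  .fpSet(m, "ecfp", "molecule",
         fingerprintSpec("ecfp", spec@ecfpRadius, spec@ecfpNbits),
         .oneBlockLayout("ecfp", spec@ecfpNbits))
}

#' Concatenate fingerprint sets into a conjoint representation
#'
#' Element-wise concatenation of the given fingerprint sets in the given
#' order; the output layout records each input block's column range so the
#' components are exactly recoverable by slicing. The default molecular
#' conjoint order is (MACCS, ECFP).
#'
#' @param ... two or more \linkS4class{FingerprintSet}s over the same
#'   records (a single set is returned relabeled, unchanged).
#' @param source provenance tag of the result (default taken from the first
#'   input).
#' @return A \linkS4class{FingerprintSet} with scheme \code{"conjoint"}.
#' @export
fpConcat <- function(..., source = NULL) {
  fps <- list(...)
  if (length(fps) == 1L && is.list(fps[[1]]) && !is(fps[[1]], "FingerprintSet"))
    fps <- fps[[1]]
  if (!length(fps)) stop("need at least one FingerprintSet")
  stopifnot(all(vapply(fps, is, logical(1), "FingerprintSet")))
  n <- nrow(fps[[1]]@bits)
  if (!all(vapply(fps, function(f) nrow(f@bits), integer(1)) == n))
    stop("all fingerprint sets must cover the same records")
  bits <- do.call(cbind, lapply(fps, fpMatrix))
  layouts <- lapply(seq_along(fps), function(k) {
    lay <- fps[[k]]@layout
    lay$block <- if (fps[[k]]@source %in% c("ligand", "pocket"))
      paste(fps[[k]]@source, lay$block, sep = ".") else lay$block
    lay
  })
  widths <- vapply(fps, function(f) ncol(f@bits), integer(1))
  off <- cumsum(c(0L, widths[-length(widths)]))
  lay <- do.call(rbind, lapply(seq_along(layouts), function(k) {
    l <- layouts[[k]]; l$start <- l$start + off[k]; l$end <- l$end + off[k]; l
  }))
  rownames(lay) <- NULL
  ecfpSpec <- Filter(function(f) f@scheme %in% c("ecfp", "conjoint"), fps)
  spec <- if (length(ecfpSpec)) ecfpSpec[[1]]@spec else fps[[1]]@spec
  .fpSet(bits, "conjoint", if (is.null(source)) fps[[1]]@source else source,
         fingerprintSpec("conjoint", spec@ecfpRadius, spec@ecfpNbits), lay)
}

#' @describeIn featurize compute the scheme of \code{spec} for a MoleculeSet:
#'   \code{"maccs"} (166 bits), \code{"ecfp"} (\code{ecfpNbits} bits) or
#'   \code{"conjoint"} (MACCS block then ECFP block).
setMethod("featurize", "MoleculeSet", function(x, spec = fingerprintSpec(), ...) {
  switch(spec@scheme,
         maccs = maccsKeys(x),
         ecfp = ecfp(x, spec),
         conjoint = fpConcat(maccsKeys(x), ecfp(x, spec)))
})

#' @describeIn featurize character SMILES vectors are wrapped into a
#'   \linkS4class{MoleculeSet} first.
setMethod("featurize", "character", function(x, spec = fingerprintSpec(), ...) {
  featurize(.asMoleculeSet(x), spec, ...)
})

.asMoleculeSet <- function(x) {
  if (is(x, "MoleculeSet")) return(x)
  if (is.character(x)) {
    ids <- if (is.null(names(x))) paste0("M", seq_along(x)) else names(x)
    return(MoleculeSet(smiles = unname(x), ids = ids))
  }
  stop("expected a MoleculeSet or character SMILES vector")
}

## ---- protein-ligand complexes -------------------------------------------

#' Extract the binding pocket of a complex
#'
#' Retains exactly those protein atoms whose minimum Euclidean distance to
#' any ligand atom is less than or equal to \code{cutoff} (closed boundary).
#' Water/metal removal has already happened at read time.
#'
#' @param cr a \linkS4class{ComplexRecord}.
#' @param cutoff pocket radius in Angstrom; default 4.5.
#' @return A \linkS4class{ComplexRecord} whose proteinAtoms are the pocket.
#' @export
extractPocket <- function(cr, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  pa <- cr@proteinAtoms
  if (nrow(pa) == 0L) return(cr)
  la <- cr@ligandAtoms
  P <- as.matrix(pa[, c("x", "y", "z")])
  L <- as.matrix(la[, c("x", "y", "z")])
  ## squared distances protein x ligand without forming an n^3 loop
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
  keep <- sqrt(pmax(apply(d2, 1, min), 0)) <= cutoff
  ComplexRecord(id = cr@id, ligandAtoms = la, proteinAtoms = pa[keep, ],
                target = cr@target)
}

## Build an OpenBabel molecule from typed 3D atoms (bond perception from
## interatomic distances); NULL for an empty atom table.
.atomsToMolRef <- function(atoms) {
  if (nrow(atoms) == 0L) return(NULL)
  el <- paste0(substr(atoms$element, 1, 1),
               tolower(substr(atoms$element, 2, 2)))
  xyz <- paste0(nrow(atoms), "\nconjointFP\n",
                paste(sprintf("%s %.4f %.4f %.4f", trimws(el),
                              atoms$x, atoms$y, atoms$z), collapse = "\n"),
                "\n")
  sdf <- ChemmineOB::convertFormat("XYZ", "SDF", xyz)
  ChemmineOB::forEachMol("SDF", sdf, identity)
}

.molRefFingerprint <- function(molRef, scheme, spec) {
  if (scheme == "maccs") {
    if (is.null(molRef)) return(integer(166))
    as.integer(ChemmineOB::fingerprint_OB(molRef, "MACCS"))[1:166]
  } else {
    if (is.null(molRef)) return(integer(spec@ecfpNbits))
    v <- as.integer(ChemmineOB::fingerprint_OB(
      molRef, paste0("ECFP", 2L * spec@ecfpRadius)))
    drop(.foldBits(matrix(v, nrow = 1), spec@ecfpNbits))
  }
}

#' Featurize a protein-ligand complex
#'
#' Converts the ligand and the extracted pocket each to the scheme's
#' fingerprint(s) and concatenates, ligand block first:
#' \itemize{
#'   \item \code{maccs}: ligand-MACCS ++ pocket-MACCS (332 bits)
#'   \item \code{ecfp}: ligand-ECFP ++ pocket-ECFP (2 x \code{ecfpNbits})
#'   \item \code{conjoint}: ligand-MACCS ++ ligand-ECFP ++ pocket-MACCS ++
#'     pocket-ECFP (4428 bits at defaults)
#' }
#' An empty pocket yields all-zero pocket blocks with a warning.
#'
#' @param cr a \linkS4class{ComplexRecord}.
#' @param spec a \linkS4class{FingerprintSpec}.
#' @param cutoff pocket radius in Angstrom (default 4.5).
#' @return A one-row \linkS4class{FingerprintSet} with source
#'   \code{"complex"}.
#' @export
featurizeComplex <- function(cr, spec = fingerprintSpec(), cutoff = 4.5) {
  pocket <- extractPocket(cr, cutoff)
  ligRef <- tryCatch(.atomsToMolRef(cr@ligandAtoms),
                     error = function(e) stop("ligand featurization failed for ",
                                              cr@id, ": ", conditionMessage(e)))
  pocketAtoms <- pocket@proteinAtoms[, c("element", "x", "y", "z")]
  if (nrow(pocketAtoms) == 0L)
    warning("empty pocket for ", cr@id, "; pocket blocks are all zeros")
  pocketRef <- tryCatch(.atomsToMolRef(pocketAtoms),
                        error = function(e) stop("pocket featurization failed for ",
                                                 cr@id, ": ", conditionMessage(e)))
  blockFor <- function(ref, schemes) {
    lapply(schemes, function(s) .molRefFingerprint(ref, s, spec))
  }
  schemes <- switch(spec@scheme, maccs = "maccs", ecfp = "ecfp",
                    conjoint = c("maccs", "ecfp"))
  blocks <- c(blockFor(ligRef, schemes), blockFor(pocketRef, schemes))
  names(blocks) <- c(paste0("ligand.", schemes), paste0("pocket.", schemes))
  widths <- vapply(blocks, length, integer(1))
  ends <- cumsum(widths)
  lay <- data.frame(block = names(blocks),
                    start = as.integer(ends - widths + 1L),
                    end = as.integer(ends))
  bits <- matrix(unlist(blocks), nrow = 1)
  rownames(bits) <- cr@id
  .fpSet(bits, spec@scheme, "complex",
         fingerprintSpec(spec@scheme, spec@ecfpRadius, spec@ecfpNbits), lay)
}

## ---- Wildman-Crippen logP baseline --------------------------------------

#' Wildman-Crippen SlogP
#'
#' Atom-contribution logP: every atom is assigned a type from the
#' Wildman-Crippen typing table and the prediction is the sum of the
#' per-type contributions (atoms outside the table fall to the method's
#' wildcard type). Deterministic and additive over disconnected fragments.
#'
#' @param x a \linkS4class{MoleculeSet} or character vector of valid SMILES.
#' @return Named numeric vector of SlogP values (logP units).
#' @examples
#' slogP(c(benzene = "c1ccccc1"))
#' @export
slogP <- function(x) {
  ms <- .asMoleculeSet(x)
  p <- .isolated(function() ChemmineR::propOB(.toSdfSet(ms@smiles, ms@ids)))
  setNames(as.numeric(p$logP), ms@ids)
}

## ---- Bemis-Murcko scaffolds ---------------------------------------------

#' Bemis-Murcko scaffold of each molecule
#'
#' The scaffold is the molecule's ring systems plus the linkers connecting
#' them: terminal (degree-1) heavy atoms are pruned iteratively until only
#' ring and linker atoms remain, and the surviving subgraph is returned as a
#' canonical SMILES. Acyclic molecules have the empty scaffold \code{""}.
#'
#' @param x a \linkS4class{MoleculeSet} or character vector of valid SMILES.
#' @return Named character vector of canonical scaffold SMILES.
#' @examples
#' murckoScaffold(c("CCc1ccccc1O", "CCO"))
#' @export
murckoScaffold <- function(x) {
  ms <- .asMoleculeSet(x)
  out <- .isolated(function() {
  sdf <- .toSdfSet(ms@smiles, ms@ids)
  vapply(seq_along(sdf), function(k) {
    one <- sdf[[k]]
    nat <- nrow(ChemmineR::atomblock(one))
    bb <- ChemmineR::bondblock(one)
    if (is.null(dim(bb)) || nrow(bb) == 0L || nat < 3L) return("")
    edges <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
    keep <- rep(TRUE, nat)
    repeat {
      deg <- tabulate(c(edges[keep[edges[, 1]] & keep[edges[, 2]], ]), nat)
      drop <- keep & deg <= 1L
      if (!any(drop)) break
      keep[drop] <- FALSE
      if (!any(keep)) break
    }
    if (!any(keep)) return("")
    sub <- ChemmineR::atomsubset(one, which(keep))
    smi <- as.character(ChemmineR::sdf2smiles(as(sub, "SDFset")))
    .canonicalSmiles(smi)
  }, character(1))
  })
  setNames(out, ms@ids)
}

## Canonical SMILES (first token of OpenBabel canonical output).
.canonicalSmiles <- function(smi) {
  out <- ChemmineOB::convertFormat("SMI", "CAN", smi)
  strsplit(trimws(out), "[ \t\n]")[[1]][1]
}
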