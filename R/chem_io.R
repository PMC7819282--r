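#' @include AllClasses.R
NULL

## Residue tags treated as water, and element symbols treated as metal ions
## when they form a single-atom residue. The deletion rule itself (waters and
## monoatomic metals are removed from pockets) follows standard practice for
## fingerprint featurization of binding sites.
.WATER_RESNAMES <- c("HOH", "WAT", "H2O")
.METAL_ELEMENTS <- c("LI", "NA", "K", "RB", "CS", "MG", "CA", "SR", "BA",
                     "MN", "FE", "CO", "NI", "CU", "ZN", "CD", "HG", "AL")

## TRUE for each SMILES that OpenBabel can parse into a molecular graph.
.parseableSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    ok <- TRUE
    tryCatch(ChemmineOB::forEachMol("SMILES", s, identity),
             error = function(e) ok <<- FALSE)
    ok
  }, logical(1), USE.NAMES = FALSE)
}

#' Read a SMILES property table (CSV)
#'
#' Reads a comma-separated table with a header row, one molecule per row.
#' Rows whose SMILES does not parse are dropped and counted in
#' \code{nFailed}, never raised; a missing file or missing column is a fatal
#' configuration error. Rows with a missing target are retained with
#' \code{NA} (and are unusable for supervised training).
#'
#' @param path CSV file path.
#' @param smilesColumn name of the SMILES column (default "smiles").
#' @param targetColumn name of the numeric property column; NULL for none.
#' @param idColumn name of the identifier column; NULL generates R1..Rn.
#' @param propertyName property label stored in the result; defaults to
#'   \code{targetColumn}.
#' @return A \linkS4class{MoleculeSet}.
#' @seealso \code{\link{writeSmilesTable}} for the inverse.
#' @export
readSmilesTable <- function(path, smilesColumn = "smiles",
                            targetColumn = NULL, idColumn = NULL,
                            propertyName = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(smilesColumn, targetColumn, idColumn)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  smiles <- as.character(tab[[smilesColumn]])
  ids <- if (is.null(idColumn)) paste0("R", seq_len(nrow(tab)))
         else as.character(tab[[idColumn]])
  target <- if (is.null(targetColumn)) rep(NA_real_, nrow(tab))
            else suppressWarnings(as.numeric(tab[[targetColumn]]))
  ok <- .parseableSmiles(smiles)
  if (any(!ok))
    message(sum(!ok), " record(s) failed to parse and were dropped")
  MoleculeSet(ids = ids[ok], smiles = smiles[ok], target = target[ok],
              propertyName = if (is.null(propertyName))
                (if (is.null(targetColumn)) "target" else targetColumn)
                else propertyName,
              nFailed = sum(!ok),
              failed = data.frame(id = ids[!ok], smiles = smiles[!ok]))
}

#' Write a MoleculeSet as a SMILES property table (CSV)
#'
#' @param ms a \linkS4class{MoleculeSet}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSmilesTable <- function(ms, path) {
  df <- data.frame(id = ms@ids, smiles = ms@smiles, target = ms@target,
                   check.names = FALSE)
  names(df)[3] <- ms@propertyName
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an SDF property dataset
#'
#' Each molecule block becomes one record; the target is parsed from the
#' named SDF data field and left \code{NA} when the field is absent.
#' Structurally invalid blocks are skipped and counted in \code{nFailed}.
#'
#' @param path SDF file path.
#' @param targetField SDF data-field name carrying the numeric property.
#' @param propertyName property label; defaults to \code{targetField}.
#' @return A \linkS4class{MoleculeSet}.
#' @export
readSdfDataset <- function(path, targetField = "logP",
                           propertyName = targetField) {
  if (!file.exists(path)) stop("file not found: ", path)
  sdf <- ChemmineR::read.SDFset(path)
  valid <- ChemmineR::validSDF(sdf)
  nfail <- sum(!valid)
  failedIds <- ChemmineR::sdfid(sdf)[!valid]
  sdf <- sdf[valid]
  if (nfail) message(nfail, " SDF block(s) were invalid and skipped")
  ids <- ChemmineR::sdfid(sdf)
  if (anyDuplicated(ids) || any(!nzchar(ids)))
    ids <- paste0("R", seq_along(sdf))
  smi <- as.character(ChemmineR::sdf2smiles(sdf))
  target <- vapply(seq_along(sdf), function(k) {
    db <- ChemmineR::datablock(sdf[[k]])
    if (targetField %in% names(db))
      suppressWarnings(as.numeric(db[[targetField]])) else NA_real_
  }, numeric(1))
  MoleculeSet(ids = ids, smiles = smi, target = target,
              propertyName = propertyName, nFailed = nfail,
              failed = data.frame(id = as.character(failedIds),
                                  smiles = rep(NA_character_, nfail)))
}

#' Write a MoleculeSet as SDF
#'
#' Targets are stored in a data field named after the property; molecules
#' without a target omit the field.
#'
#' @param ms a \linkS4class{MoleculeSet}.
#' @param path output SDF path.
#' @return \code{path}, invisibly.
#' @export
writeSdfDataset <- function(ms, path) {
  sdf <- ChemmineR::smiles2sdf(setNames(ms@smiles, ms@ids))
  ChemmineR::datablock(sdf) <- lapply(seq_along(sdf), function(k) {
    db <- c(cid = ms@ids[k])
    if (!is.na(ms@target[k]))
      db[[ms@propertyName]] <- format(ms@target[k], digits = 15)
    db
  })
  ChemmineR::write.SDF(sdf, file = path, cid = TRUE)
  invisible(path)
}

## Parse PDB-style atom records into a data.frame(element, resname, x, y, z).
.readPdbAtoms <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  el <- toupper(trimws(at$elesy))
  ## fall back to the first letter of the atom name when the element column
  ## is blank (common in hand-written toy files)
  blank <- is.na(el) | !nzchar(el)
  el[blank] <- toupper(substr(trimws(at$elety[blank]), 1, 1))
  data.frame(element = el, resname = toupper(trimws(at$resid)),
             resno = at$resno, x = at$x, y = at$y, z = at$z,
             stringsAsFactors = FALSE)
}

#' Read a protein-ligand complex from PDB-style files
#'
#' Consumes only element symbol, residue tag and coordinates. Water
#' molecules (residue tag HOH/WAT/H2O) and monoatomic metal-ion residues are
#' deleted from the protein atoms; ligand atoms are kept verbatim. An empty
#' ligand is fatal.
#'
#' @param pathProtein PDB file with the protein atoms.
#' @param pathLigand PDB file with the ligand atoms.
#' @param id complex identifier; defaults to the ligand file stem.
#' @param target pKi value or NA.
#' @return A \linkS4class{ComplexRecord}.
#' @export
readComplex <- function(pathProtein, pathLigand,
                        id = sub("[.][^.]*$", "", basename(pathLigand)),
                        target = NA_real_) {
  prot <- .readPdbAtoms(pathProtein)
  lig <- .readPdbAtoms(pathLigand)
  if (nrow(lig) == 0L) stop("empty ligand in ", pathLigand)
  keep <- !(prot$resname %in% .WATER_RESNAMES)
  ## monoatomic residues of metallic elements
  resSize <- table(paste(prot$resname, prot$resno))
  mono <- resSize[paste(prot$resname, prot$resno)] == 1L
  keep <- keep & !(mono & prot$element %in% .METAL_ELEMENTS)
  ComplexRecord(id = id,
                ligandAtoms = lig[, c("element", "x", "y", "z")],
                proteinAtoms = prot[keep, c("element", "resname", "x", "y", "z")],
                target = target)
}

#' Write a ComplexRecord as a pair of PDB-style files
#'
#' @param cr a \linkS4class{ComplexRecord}.
#' @param dir output directory (created if needed).
#' @return character(2): protein and ligand file paths, invisibly.
#' @export
writeComplex <- function(cr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(atoms, rec, resnames, resnos) {
    vapply(seq_len(nrow(atoms)), function(k) {
      sprintf("%-6s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
              rec, k, substr(atoms$element[k], 1, 2), resnames[k], resnos[k],
              atoms$x[k], atoms$y[k], atoms$z[k], atoms$element[k])
    }, character(1))
  }
  pa <- cr@proteinAtoms
  protPath <- file.path(dir, paste0(cr@id, "_protein.pdb"))
  ligPath <- file.path(dir, paste0(cr@id, "_ligand.pdb"))
  writeLines(c(fmt(pa, "ATOM", pa$resname, seq_len(nrow(pa))), "END"), protPath)
  la <- cr@ligandAtoms
  writeLines(c(fmt(la, "HETATM", rep("LIG", nrow(la)), rep(1L, nrow(la))), "END"),
             ligPath)
  invisible(c(protein = protPath, ligand = ligPath))
}

#' Write a featurized dataset as a dense CSV matrix plus a JSON sidecar
#'
#' The matrix file holds one row per record (id column first, then one
#' column per bit); the sidecar records the fingerprint spec, block layout
#' and engine provenance so a model never sees a mixed layout.
#'
#' @param fps a \linkS4class{FingerprintSet}.
#' @param prefix output path prefix; writes \code{<prefix>_matrix.csv} and
#'   \code{<prefix>_meta.json}.
#' @param targets optional named numeric vector written into the matrix file.
#' @return character(2) of written paths, invisibly.
#' @export
writeFingerprintSet <- function(fps, prefix, targets = NULL) {
  m <- fps@bits
  df <- data.frame(id = rownames(m), check.names = FALSE)
  if (!is.null(targets)) df$target <- as.numeric(targets[rownames(m)])
  df <- cbind(df, as.data.frame(m))
  names(df)[(ncol(df) - ncol(m) + 1):ncol(df)] <- paste0("b", seq_len(ncol(m)))
  mpath <- paste0(prefix, "_matrix.csv")
  jpath <- paste0(prefix, "_meta.json")
  utils::write.csv(df, mpath, row.names = FALSE, quote = FALSE)
  meta <- list(scheme = fps@scheme, source = fps@source,
               ecfpRadius = fps@spec@ecfpRadius, ecfpNbits = fps@spec@ecfpNbits,
               maccsNbits = fps@spec@maccsNbits, layout = fps@layout,
               engine = "OpenBabel via ChemmineOB",
               nRecords = nrow(m), nBits = ncol(m))
  jsonlite::write_json(meta, jpath, auto_unbox = TRUE, digits = NA)
  invisible(c(matrix = mpath, meta = jpath))
}

#' Read a featurized dataset written by \code{writeFingerprintSet}
#'
#' @param prefix the path prefix used at write time.
#' @return A list with elements \code{fps} (\linkS4class{FingerprintSet}) and
#'   \code{targets} (named numeric or NULL).
#' @export
readFingerprintSet <- function(prefix) {
  mpath <- paste0(prefix, "_matrix.csv")
  jpath <- paste0(prefix, "_meta.json")
  if (!file.exists(mpath) || !file.exists(jpath))
    stop("missing matrix or sidecar for prefix ", prefix)
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  df <- utils::read.csv(mpath, check.names = FALSE)
  targets <- NULL
  bitStart <- 2L
  if ("target" %in% names(df)) {
    targets <- setNames(df$target, df$id)
    bitStart <- 3L
  }
  m <- as.matrix(df[, bitStart:ncol(df), drop = FALSE])
  rownames(m) <- df$id
  colnames(m) <- NULL
  spec <- fingerprintSpec(scheme = meta$scheme, ecfpRadius = meta$ecfpRadius,
                          ecfpNbits = meta$ecfpNbits)
  lay <- as.data.frame(meta$layout)
  lay$start <- as.integer(lay$start); lay$end <- as.integer(lay$end)
  list(fps = .fpSet(m, meta$scheme, meta$source, spec, lay),
       targets = targets)
}
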