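#' @include AllClasses.R AllGenerics.R fingerprints.R splitters.R
NULL

## Fragment pool: ring systems are concatenation-safe SMILES (appending text
## bonds to the ring-closure atom); chainable substituents end in an atom
## with a free valence; terminal substituents close a chain.
.RING_FRAGMENTS <- c(
  "c1ccccc1", "C1CCCCC1", "c1ccncc1", "c1cncnc1", "c1ccc2ccccc2c1",
  "C1CCNCC1", "C1CCOCC1", "C1CCNC1", "C1CCOC1", "c1ccsc1", "c1ccoc1",
  "c1cc[nH]c1")
.CHAIN_FRAGMENTS <- c(
  "C", "CC", "CCC", "CO", "CN", "OC", "NC", "CCO", "C(C)C", "COC",
  "C(=O)C", "S", "C=C", "CC(C)")
.TERMINAL_FRAGMENTS <- c(
  "F", "Cl", "Br", "C#N", "C(=O)O", "C(=O)N", "C(F)(F)F", "O", "N")

#' Configuration of the synthetic benchmark generator
#'
#' Bundles every knob of the synthetic study: how many molecules to
#' assemble, which fragment pool to draw from, which fingerprint bits carry
#' planted signal in the MACCS and ECFP blocks, the per-bit effect sizes,
#' the Gaussian noise level and the seed. The defaults emulate a
#' lipophilicity-style regression with signal deliberately split across the
#' two fingerprint blocks (so neither standalone representation can see all
#' of it) and noise on the scale of an "acceptable" prediction deviation
#' (0.5 log units).
#'
#' @param nMolecules number of molecules (default 500).
#' @param fragmentPool list with elements \code{rings}, \code{chains},
#'   \code{terminals} of valid SMILES fragments.
#' @param signalBitsMaccs,signalBitsEcfp integer bit indices (1-based within
#'   each block) carrying signal; NULL (default) auto-selects 3 bits per
#'   block at generation time: bits with prevalence in [0.25, 0.75] whose
#'   maximum absolute correlation with every bit of the other block is
#'   smallest, so each block holds information the other cannot proxy.
#' @param effectSizes numeric effects, one per signal bit (MACCS bits first);
#'   default alternates +1/-1.
#' @param noiseSd Gaussian noise standard deviation in property units
#'   (default 0.5).
#' @param seed integer seed; every stochastic choice flows from it.
#' @return A list of class \code{syntheticConfig}.
#' @export
syntheticConfig <- function(nMolecules = 500L, fragmentPool = NULL,
                            signalBitsMaccs = NULL, signalBitsEcfp = NULL,
                            effectSizes = NULL, noiseSd = 0.5, seed = 1L) {
  if (is.null(fragmentPool))
    fragmentPool <- list(rings = .RING_FRAGMENTS, chains = .CHAIN_FRAGMENTS,
                         terminals = .TERMINAL_FRAGMENTS)
  stopifnot(length(fragmentPool$rings) > 0, noiseSd >= 0)
  if (!is.null(signalBitsMaccs) && any(signalBitsMaccs < 1 | signalBitsMaccs > 166))
    stop("signalBitsMaccs out of range for a 166-bit block")
  structure(list(nMolecules = as.integer(nMolecules),
                 fragmentPool = fragmentPool,
                 signalBitsMaccs = signalBitsMaccs,
                 signalBitsEcfp = signalBitsEcfp,
                 effectSizes = effectSizes, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "syntheticConfig")
}

## Deterministic list of distinct scaffold assemblies: single rings first,
## then linked ring pairs, guaranteeing >= ceiling(n/10) distinct
## Bemis-Murcko scaffolds in a generated set.
.scaffoldAssemblies <- function(pool) {
  rings <- pool$rings
  singles <- rings
  pairs <- unlist(lapply(seq_along(rings), function(i)
    vapply(seq(i, length(rings)), function(j)
      paste0(rings[i], "C", rings[j]), character(1))))
  c(singles, pairs)
}

#' Generate synthetic drug-like molecules
#'
#' Assembles molecules by seeded combinatorial joining of pool fragments:
#' a ring system (or a linked ring pair), a chain of 0--2 chainable
#' substituents and optionally one terminal group, attached by single bonds
#' at open valences. The first \code{ceiling(n/10)} molecules walk a
#' deterministic list of distinct ring assemblies so scaffold splitting is
#' always exercised. Every emitted SMILES parses; an assembly that fails to
#' parse is retried with fresh draws.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return A \linkS4class{MoleculeSet} with ids SYN0001... and NA targets.
#' @export
genMolecules <- function(cfg) {
  pool <- cfg$fragmentPool
  n <- cfg$nMolecules
  forced <- .scaffoldAssemblies(pool)
  nForced <- min(ceiling(n / 10), length(forced))
  .withSeed(cfg$seed, {
    smiles <- character(n)
    for (k in seq_len(n)) {
      for (attempt in 1:20) {
        core <- if (k <= nForced) forced[k]
        else if (stats::runif(1) < 0.5)
          paste0(sample(pool$rings, 1),
                 sample(c("", pool$chains), 1), sample(pool$rings, 1))
        else sample(pool$rings, 1)
        nChain <- sample(0:2, 1)
        s <- paste0(core, paste(sample(pool$chains, nChain, replace = TRUE),
                                collapse = ""))
        if (stats::runif(1) < 0.4) s <- paste0(s, sample(pool$terminals, 1))
        if (.parseableSmiles(s)) break
        s <- NA_character_
      }
      if (is.na(s)) stop("could not assemble a valid molecule after 20 tries")
      smiles[k] <- s
    }
    MoleculeSet(smiles = smiles, ids = sprintf("SYN%04d", seq_len(n)),
                propertyName = "logP_sim",
                metadata = list(generator = "conjointFP::genMolecules",
                                seed = cfg$seed))
  })
}

## Auto-select signal bits: candidates with prevalence in [0.25, 0.75],
## ranked by the maximum absolute cross-block correlation (ascending), so
## the chosen bits are the hardest to proxy from the other block.
.pickSignalBits <- function(block, otherBlock, k = 3L) {
  p <- colMeans(block)
  cand <- which(p >= 0.25 & p <= 0.75)
  if (length(cand) < k) cand <- order(abs(p - 0.5))[seq_len(max(k, 10L))]
  pOther <- colMeans(otherBlock)
  varying <- otherBlock[, pOther > 0 & pOther < 1, drop = FALSE]
  crossCor <- abs(stats::cor(block[, cand, drop = FALSE], varying))
  maxCor <- apply(crossCor, 1, max)
  cand[order(maxCor, cand)][seq_len(k)]
}

#' Plant block-structured signal targets onto a molecule set
#'
#' Computes the MACCS and ECFP blocks, chooses (or takes from the config)
#' signal bits in each block, and sets each molecule's target to
#' \code{sum(effect_i * bit_i) + N(0, noiseSd)}. Because part of the signal
#' lives only in the MACCS block and part only in the ECFP block, the two
#' fingerprints are complementary by construction: a model that sees both
#' blocks can explain variance that neither standalone representation can.
#'
#' @param ds a \linkS4class{MoleculeSet} (targets are overwritten).
#' @param cfg a \code{\link{syntheticConfig}}.
#' @param spec \linkS4class{FingerprintSpec} used for the blocks.
#' @return A \linkS4class{MoleculeSet} whose \code{metadata$signal} records
#'   the chosen bits, effects and noise level.
#' @export
genTargets <- function(ds, cfg, spec = fingerprintSpec()) {
  Xm <- fpMatrix(maccsKeys(ds))
  Xe <- fpMatrix(ecfp(ds, spec))
  bitsM <- cfg$signalBitsMaccs
  bitsE <- cfg$signalBitsEcfp
  if (is.null(bitsM)) bitsM <- .pickSignalBits(Xm, Xe)
  if (is.null(bitsE)) bitsE <- .pickSignalBits(Xe, Xm)
  eff <- cfg$effectSizes
  if (is.null(eff)) eff <- rep(c(1, -1), length.out = length(bitsM) + length(bitsE))
  stopifnot(length(eff) == length(bitsM) + length(bitsE))
  effM <- eff[seq_along(bitsM)]
  effE <- eff[length(bitsM) + seq_along(bitsE)]
  signal <- drop(Xm[, bitsM, drop = FALSE] %*% effM +
                 Xe[, bitsE, drop = FALSE] %*% effE)
  y <- .withSeed(cfg$seed + 1L,
                 signal + stats::rnorm(length(signal), 0, cfg$noiseSd))
  MoleculeSet(smiles = ds@smiles, ids = ds@ids, target = y,
              propertyName = ds@propertyName, nFailed = ds@nFailed,
              failed = ds@failed,
              metadata = c(ds@metadata,
                           list(signal = list(bitsMaccs = bitsM,
                                              bitsEcfp = bitsE,
                                              effectsMaccs = effM,
                                              effectsEcfp = effE,
                                              noiseSd = cfg$noiseSd))))
}

#' Generate toy protein-ligand complexes
#'
#' Each complex is a fragment-assembled ligand laid out in the z = 0 plane
#' (2D depiction coordinates scaled to bonding distances) plus protein-like
#' atoms placed at seeded distances spanning 2--8 Angstrom from the ligand.
#' Construction guarantees at least one protein atom inside and one outside
#' the 4.5 Angstrom pocket cutoff, and includes two waters (residue HOH)
#' and one zinc ion so the read-time deletion rules are exercised.
#'
#' @param n number of complexes.
#' @param seed integer seed.
#' @return A list of \linkS4class{ComplexRecord}s with simulated pKi targets.
#' @export
genComplexes <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  pool <- list(rings = .RING_FRAGMENTS, chains = .CHAIN_FRAGMENTS)
  .withSeed(seed, {
    lapply(seq_len(n), function(k) {
      smi <- paste0(sample(pool$rings, 1), sample(c("", pool$chains), 1))
      sdf <- ChemmineR::smiles2sdf(smi)[[1]]
      ab <- ChemmineR::atomblock(sdf)
      lig <- data.frame(element = gsub("_.*", "", rownames(ab)),
                        x = ab[, 1] * 1.5, y = ab[, 2] * 1.5, z = 0)
      cen <- colMeans(lig[, c("x", "y", "z")])
      rmax <- max(sqrt(colSums((t(lig[, c("x", "y", "z")]) - cen)^2)))
      placeNear <- function(dist, element, resname) {
        a <- lig[sample.int(nrow(lig), 1), ]
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        data.frame(element = element, resname = resname,
                   x = a$x + dist * u[1], y = a$y + dist * u[2],
                   z = a$z + dist * u[3])
      }
      placeFar <- function(dist, element, resname) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        data.frame(element = element, resname = resname,
                   x = cen[1] + (rmax + dist) * u[1],
                   y = cen[2] + (rmax + dist) * u[2],
                   z = cen[3] + (rmax + dist) * u[3])
      }
      nExtra <- sample(6:10, 1)
      prot <- rbind(
        placeNear(stats::runif(1, 2, 4), "C", "ALA"),      # guaranteed inside
        placeFar(6, "C", "GLY"),                            # guaranteed outside
        do.call(rbind, lapply(seq_len(nExtra), function(j)
          placeNear(stats::runif(1, 2, 8),
                    sample(c("C", "N", "O", "S"), 1),
                    sample(c("ALA", "GLY", "SER", "LEU", "VAL"), 1)))),
        placeNear(stats::runif(1, 2.5, 4), "O", "HOH"),
        placeNear(stats::runif(1, 2.5, 4), "O", "HOH"),
        placeNear(stats::runif(1, 2, 3.5), "ZN", "ZN"))
      ComplexRecord(id = sprintf("CPX%03d", k), ligandAtoms = lig,
                    proteinAtoms = prot, target = stats::runif(1, 3, 10))
    })
  })
}
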