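## Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

## A small planted-signal dataset used across test files.
testDataset <- function(n = 120L, seed = 11L, noiseSd = 0.5) {
  key <- sprintf("ds_%d_%d_%g", n, seed, noiseSd)
  if (is.null(.fixtureCache[[key]])) {
    cfg <- syntheticConfig(nMolecules = n, noiseSd = noiseSd, seed = seed)
    .fixtureCache[[key]] <- genTargets(genMolecules(cfg), cfg)
  }
  .fixtureCache[[key]]
}

## Conjoint features + targets for the test dataset.
testFeatures <- function(n = 120L, seed = 11L, noiseSd = 0.5) {
  key <- sprintf("fp_%d_%d_%g", n, seed, noiseSd)
  if (is.null(.fixtureCache[[key]])) {
    ms <- testDataset(n, seed, noiseSd)
    .fixtureCache[[key]] <- list(ms = ms, fps = featurize(ms),
                                 y = unname(molTargets(ms)))
  }
  .fixtureCache[[key]]
}

## Reference-engine MACCS on-bit panel (computed independently with RDKit
## GenMACCSKeys; key numbers are 1-based dictionary positions).
rdkitMaccsPanel <- function() {
  list(
    benzene = list(smiles = "c1ccccc1", bits = c(162, 163, 165)),
    ethanol = list(smiles = "CCO",
                   bits = c(82, 109, 114, 139, 153, 155, 157, 160, 164)),
    aspirin = list(smiles = "CC(=O)Oc1ccccc1C(=O)O",
                   bits = c(89, 113, 123, 126, 127, 136, 139, 140, 143, 144,
                            146, 150, 152, 154, 157, 159, 160, 162, 163, 164,
                            165)),
    nicotine = list(smiles = "CN1CCC[C@H]1c1cccnc1",
                    bits = c(62, 65, 75, 80, 83, 85, 86, 93, 96, 98, 100, 108,
                             111, 115, 116, 118, 120, 121, 122, 129, 137, 142,
                             147, 148, 150, 153, 156, 158, 160, 161, 162, 163,
                             165)),
    cyclohexane = list(smiles = "C1CCCCC1",
                       bits = c(118, 128, 129, 147, 163, 165)),
    benzamide = list(smiles = "O=C(N)c1ccccc1",
                     bits = c(84, 92, 110, 117, 151, 154, 156, 158, 161, 162,
                              163, 164, 165)),
    toluene = list(smiles = "Cc1ccccc1", bits = c(160, 162, 163, 165)),
    phenol = list(smiles = "Oc1ccccc1",
                  bits = c(113, 127, 139, 143, 152, 157, 162, 163, 164, 165)),
    hexane = list(smiles = "CCCCCC",
                  bits = c(108, 114, 115, 116, 118, 129, 147, 149, 155, 160)),
    diethyl_ether = list(smiles = "CCOCC",
                         bits = c(86, 109, 114, 116, 126, 138, 149, 153, 155,
                                  157, 160, 164)),
    pyridine = list(smiles = "c1ccncc1",
                    bits = c(65, 98, 121, 137, 161, 162, 163, 165)))
}

## Reference Wildman-Crippen SlogP values (computed independently with
## RDKit Crippen.MolLogP on molecules where atom typing is uncontentious).
rdkitSlogpPanel <- function() {
  c(benzene = 1.6866, ethanol = -0.0014, aspirin = 1.3101,
    cyclohexane = 2.3406, toluene = 1.9950, phenol = 1.3922,
    naphthalene = 2.8398, hexane = 2.5866, diethyl_ether = 1.0428,
    pyridine = 1.0816)
}

slogpPanelSmiles <- function() {
  c(benzene = "c1ccccc1", ethanol = "CCO", aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    cyclohexane = "C1CCCCC1", toluene = "Cc1ccccc1", phenol = "Oc1ccccc1",
    naphthalene = "c1ccc2ccccc2c1", hexane = "CCCCCC",
    diethyl_ether = "CCOCC", pyridine = "c1ccncc1")
}

## Brute-force pocket filter oracle: per-atom double loop over all pairs.
bruteForcePocket <- function(cr, cutoff) {
  pa <- cr@proteinAtoms; la <- cr@ligandAtoms
  keep <- logical(nrow(pa))
  for (i in seq_len(nrow(pa))) {
    dmin <- Inf
    for (j in seq_len(nrow(la)))
      dmin <- min(dmin, sqrt((pa$x[i] - la$x[j])^2 + (pa$y[i] - la$y[j])^2 +
                             (pa$z[i] - la$z[j])^2))
    keep[i] <- dmin <= cutoff
  }
  keep
}
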