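---
title: "Conjoint molecular fingerprints: model, protocol and design notes"
author: "conjointFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conjoint molecular fingerprints: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The representation problem

QSAR/QSPR regression starts from a fixed-length numeric encoding of a
molecule. The two workhorse encodings capture different things:

* **MACCS keys** (166 bits) answer "which of 166 predefined substructure
  patterns occur in this molecule?" They carry atom- and bond-type
  information but almost no connectivity context.
* **ECFP** (extended-connectivity fingerprints) hash each atom's
  neighborhood out to a bond radius (2 here) into integer identifiers and
  fold them onto a fixed-width bit vector (2048 here). They carry local
  topology but no curated chemical-pattern dictionary.

Because the two encodings are complementary, this package implements and
evaluates the *conjoint* fingerprint: the plain concatenation
MACCS ++ ECFP, a 2214-bit vector, fed to a regressor as a single input.
The package's benchmarking protocol compares, for each regressor family,
four representations: each standalone fingerprint, the conjoint vector,
and a *consensus* ensemble that trains one model per standalone
fingerprint and averages their predictions (unweighted mean; the
two members always share family and training rows).

For protein--ligand affinity (pKi) the same idea is applied to a complex:
the ligand and the binding pocket -- every protein atom within 4.5
Angstrom of any ligand atom, after waters and monoatomic metal ions are
removed at read time -- are each fingerprinted and concatenated
(ligand blocks first, then pocket blocks; for the conjoint scheme the
layout is ligand-MACCS ++ ligand-ECFP ++ pocket-MACCS ++ pocket-ECFP,
4428 bits). The block layout travels with every
`FingerprintSet` so a model never sees two different layouts.

## Regressor families

Five families share one train/predict contract (`trainModel` /
`predictTarget`), all seeded so a run is exactly replayable:

* **rf** -- random forest (`randomForest`); defaults ntree = 300,
  mtry = p/3, nodesize = 5.
* **svr** -- epsilon-SVR with the RBF kernel (`e1071`), C = 5,
  gamma = 0.015, inputs unscaled (they are bits). A constant training
  target is a degenerate corner of the SVR formulation (no support
  vectors) and is fitted as the exact constant predictor.
* **xgb** -- gradient-boosted trees (`xgboost`, `xgb.train` API);
  defaults nrounds = 200, max depth = 6, eta = 0.1, single thread.
* **dnn** -- a feed-forward network: one hidden layer (width 100, relu,
  inverted dropout 0.1 by default), scalar linear output, Adam at
  learning rate 0.001, minibatch 32, 100 epochs.
* **lstm** -- the input vector treated as one time step through two LSTM
  layers (first layer width = input width, matching the architecture it
  reproduces), then a dense relu layer and a scalar output.

The neural engine is written directly in R matrix algebra (Glorot-uniform
hidden weights, zero-initialized output layer, bias-corrected Adam). Two
numerical choices matter and are deliberate:

* Targets are mean-centered for the neural families and the mean is
  restored at prediction. With Adam's step size capped near the learning
  rate, an uncentered target of mean `m` would need on the order of
  `|m|/lr` updates just to move the output bias; centering (with a
  zero-initialized output layer) makes the untrained network the
  target-mean predictor, which is the right starting point for
  regression.
* The per-epoch training loss recorded in `lossHistory` is the running
  mean of minibatch losses seen during the epoch -- the usual epoch-loss
  bookkeeping of deep-learning frameworks -- and the validation loss is a
  full pass. Loss histories have exactly one row per epoch; there is no
  early stopping (epoch count is a searched hyperparameter, not a
  stopping rule).

RF and XGB defaults are package choices exposed for tuning; they are not
claimed to equal any externally tuned values. SVR's C = 5 / gamma = 0.015
are fixed defaults of the protocol this package implements.

## Splitting protocol

`randomSplit` reproduces the 20% test / 4:1 train:validation protocol:
`|test| = round(0.2 n)`, then `|val| = round(rest/5)`, remainder train.
Rounding had to be pinned somewhere; round-half-even on the test quota
first, then on the validation quota, is the frozen convention.
`repeatedTrials` derives trial `i` from seed `base + i - 1`, so trial 1
is exactly the single split at the base seed.

`scaffoldSplit` groups molecules by Bemis--Murcko scaffold (ring systems
plus linkers; computed by iteratively pruning degree-1 heavy atoms and
canonicalizing the surviving subgraph -- exocyclic substituents,
including =O decorations, are treated as side chains and pruned, which is
the pure graph-topology reading of the scaffold). Groups are assigned
whole, largest first (ties by scaffold string), filling train, then
validation, then test; the split is deterministic and seedless, and no
scaffold can appear in two partitions. Whether the original protocol's
scaffold split kept a validation partition is not stated anywhere we
could verify; mirroring the random protocol's 4:1 inner split was the
choice made here.

## Tuning

`gridSearch` evaluates the full Cartesian grid with k-fold
cross-validation (5 folds by default; folds are a seeded shuffle dealt
round-robin, so sizes differ by at most one) and scores candidates by
mean negative MSE. Ties break toward the smaller model -- capacity is a
per-family proxy: hidden width (dnn), ntree (rf), nrounds x 2^depth
(xgb), C (svr) -- then grid order. A candidate that fails to train is
scored as worst and logged, never fatal: large neural grids contain
degenerate corners and a search must survive them. The search never sees
the held-out test partition; `cmdTune` enforces this structurally by
splitting first and tuning inside the non-test portion only. The default
DNN grid spans hidden widths {10, 20, 40, 50, 60, 100, 300, 500},
activations {softsign, relu, linear, tanh} and dropout 0--0.6 in steps
of 0.1; batch-size and epoch candidate lists are package choices, since
no authoritative list exists to mirror.

## Metrics

`mse`, `rmse` and `pearsonR` implement the textbook formulas directly;
`pearsonR` refuses constant vectors rather than returning a silent 0.
The correlation reported as "pearson" is the *unsquared* r (the quantity
the printed formula computes, even where the field's tables label it
R^2); `pearsonR2` is exported separately so both conventions are
available. Deviation bins follow the Tetko classification of
|error| in logP units: acceptable (at most 0.5), disputable ((0.5, 1]),
unacceptable (> 1). The shared endpoints are ambiguous in the prose this
follows; the frozen convention is closed on the left bin (0.5 is
acceptable, 1.0 is disputable). `aggregateReports` reports mean and
sample standard deviation across repeated trials (a single trial reports
spread 0). `pcaProject` is mean-centered PCA via `prcomp`, used to
compare how much chemical space each scheme spreads data over.

## The synthetic study

Real lipophilicity and affinity datasets are licensed downloads, so the
package carries a generator that emulates the *structure* of those
studies without any external file.

* `genMolecules` assembles drug-like molecules from a ~35-fragment pool
  (12 ring systems, chainable substituents, terminal groups) by seeded
  string concatenation at open valences; every emitted SMILES parses.
  The first ceiling(n/10) molecules walk a deterministic list of distinct
  ring assemblies, so a 200-molecule set always has at least 20 distinct
  Bemis--Murcko scaffolds and scaffold splitting is genuinely exercised.
* `genTargets` plants block-structured signal: three bits in the MACCS
  block and three in the ECFP block (auto-selected among bits with
  prevalence 0.25--0.75 to be maximally *uncorrelated* with the other
  block, so neither block can proxy the other's signal), effects
  alternating +1/-1, plus Gaussian noise with sd 0.5 -- the scale of one
  "acceptable" deviation bin. The design is recorded in
  `metadata(ms)$signal`.
* `genComplexes` builds toy 3D complexes: a fragment ligand in the z = 0
  plane (depiction coordinates scaled to bonding distances; pocket
  featurization perceives bonds from interatomic distances), protein
  atoms at seeded distances spanning 2--8 Angstrom with at least one atom
  guaranteed inside and one outside the 4.5 Angstrom cutoff, two waters
  and a zinc ion to exercise the read-time deletion rules.

What passing on this generator shows -- and what it does not. The planted
design makes "the two blocks are complementary" true *by construction*,
so the ordering experiment (below) tests whether the machinery can
exploit complementarity when it exists, with realistic bit sparsity and
bit correlations inherited from real fragment chemistry. It does not show
that real logP data has that structure, that effect sizes are linear in
single bits, or anything about measurement noise beyond its scale; those
claims belong to benchmarks on the original datasets, which require
downloads this package deliberately does not perform.

The package's self-contained analogue of the central claim is the
**planted-signal ordering experiment**: 500 molecules, noise sd 0.5,
10 repeated random splits; for SVR and DNN the mean held-out Pearson r
must satisfy conjoint > max(maccs, ecfp) and conjoint >= consensus. It is
asserted in `tests/testthat/test-acceptance.R` and recomputed from
scratch by `scripts/acceptance.R`. Problem sizes throughout the test
suite (60--500 molecules, 10 trials, 2-point demonstration grids) are the
package's documented study conditions for desk-scale replication.

## Engine notes and limitations

Chemistry (SMILES/SDF parsing, substructure matching, circular
fingerprints, canonical SMILES, Wildman--Crippen logP) is delegated to
Open Babel through ChemmineR/ChemmineOB. Three consequences are worth
knowing:

* The 166-key MACCS output was verified bit-for-bit against an
  independent implementation on a reference panel; the exception is key
  125 (an aromatic-ring-count pattern), where engines disagree on
  multi-ring systems. Keys the engine cannot match stay 0, constantly.
* ECFP identifiers are engine-specific: two engines' circular
  fingerprints are not bit-compatible even at the same radius and width.
  Cross-engine checks therefore test engine-independent properties
  (atom-order invariance, the radius-0 subset relation, folding
  identities) rather than bit equality. The unfolded width is 4096;
  requested widths must be powers of two and are reached by OR-folding
  halves.
* `slogP` is the Wildman--Crippen atom-contribution method as
  implemented by the engine. Its typing table revision differs from
  other implementations for some nitrogen environments (amides, tertiary
  amines); agreement is exact (1e-4) on C/O/aromatic-N chemistry and the
  test panel pins those values.

Batch engine calls are evaluated in short-lived forked child processes
because the engine retains per-molecule native memory for the lifetime of
the process; isolation keeps long benchmark runs flat in memory. On
platforms without fork the calls run in-process with the same results.

Other limitations, deliberate: no salt stripping, neutralization or
tautomer standardization before featurization (inputs are taken as
written); pockets are filtered by atom, not by whole residue; no
count-based or 3D fingerprint variants; no significance testing between
representations -- the benchmark reports means and spreads, not p-values.
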