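---
title: "Orthologue-aware target prediction: methods and design"
author: "orthotarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthologue-aware target prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthotarget)
```

## The problem

Ligand-based target prediction trains one binary classifier per protein
target on the fingerprints of its known active and inactive compounds,
then scores untested compounds across all targets to propose a
mode-of-action hypothesis. Models restricted to a single species discard
the measurements made on *orthologues* — the closest relatives of a gene
in other species, which usually conserve function and often bind the
same chemotypes. This package implements the full workflow for testing
and exploiting that assumption: it curates cross-species bioactivity
tables, audits how often human and orthologue annotations actually
disagree, quantifies how much new chemical space orthologue ligands
contribute, merges them into human training sets, and measures the
effect on predictive performance under a chronological cross-validation
that mimics prospective use.

## Curation model

Activity is expressed on the pChEMBL scale, the negative decadic
logarithm of a molar Ki/Kd/IC50/EC50; 10 µM corresponds to pChEMBL 5,
the conventional activity cut-off used throughout
(`curation_config()$pchembl_active_min`). Records qualify as active when
they come from binding or functional assays with an assay-to-target
confidence score strictly above 5 (so measurements on protein complexes
are retained while poorly mapped assays are not) and either reach the
affinity cut-off or carry an explicit "active" comment — the route taken
by percentage activation/inhibition endpoints, which have no affinity
value and contribute a label only. Units without a fixed molar
conversion are rejected rather than guessed.

Structures are normalised before any comparison: the largest fragment
is kept (counter-ions and solvents dropped; ties broken by heavy-atom
count, then lexicographic order of the canonical SMILES), ±1 charges
are neutralised where valence allows, explicit hydrogens removed, and
the result written as an Open Babel canonical SMILES. The operation is
idempotent, which the test suite asserts on generated libraries.
Tautomer canonicalisation is *not* performed — the toolkit exposes no
tautomer normaliser — so two inputs drawn as different tautomers of one
compound can in principle survive as distinct structures; aromatic
perception canonicalises the common mesomeric cases. Compounds are then
filtered to drug-like inorganic-free chemistry: carbon required,
molecular weight within [100, 1000] Da, and no atom with atomic number
in 21–32, 36–52 or ≥ 54. "Greater than 53" is read as forbidding Z ≥ 54,
so iodine (Z = 53) passes; this matches the prevalence of iodinated drug
candidates. Within one (structure, target, species) triple, duplicate
measurements collapse to the earliest record so that the time-series
split later sees each structure at its first appearance. When the same
(structure, target) pair is active in the curated, manually maintained
source and inactive in the screening-derived source, the active
annotation wins.

## Orthologue mapping and audits

Homology groups in the HomoloGene layout (group id, taxon, accession,
protein-change ratio) are expanded into human–orthologue accession
pairs. Orthologue actives are re-assigned to the mapped human accession
with removal of duplicate SMILES, keeping the human-provenance copy;
targets are then filtered for a minimum of 10 actives
(`min_actives`), and targets that pass only thanks to orthologue
additions are reported as *newly enabled* — models that could not exist
from human data alone.

Three audits quantify the risk of the transfer:

* **Conflicts** — a mapped record conflicts when the identical
  standardized SMILES carries the opposite annotation at the mapping
  partner. Identity is exact string equality of canonical SMILES (no
  similarity fuzz), and counting is mapping-level: a compound measured
  at an accession involved in several mappings counts once per mapping.
  The report carries per-mapping `(n_mapped, n_conflicting)` rows, the
  compatibility percentage `100·(1 − N_conflicting/N_mapped)`, and the
  fraction of mappings free of conflicts. Both published directions are
  expressed through the argument roles: orthologue actives against human
  inactives, and mapped screening inactives against curated actives.
* **Concordance** — for compounds measured at both partners, the squared
  Pearson correlation of the paired pChEMBL values (overall and per
  units × type × assay group, matching the regression-line framing of
  the source analyses; groups under 3 pairs report `NA`, never zero),
  the median absolute discordance in pChEMBL units, and the fraction of
  pairs active in both species at the cut-off.
* **Protein-change binning** — discordance binned by the homology
  group's amino-acid change ratio (bin width 0.1, mirroring the
  published 0.1/0.2/0.3/0.4 bins), with a trend statistic defined as the
  squared Pearson correlation between ratio and absolute discordance;
  constant discordance reads as trend 0.

Chemical space is summarised by nearest-neighbour (NN) Tanimoto
similarity on 2048-bit ECFP_4 fingerprints: for each orthologue active,
the maximum similarity to the same target's human actives, and the
leave-one-out maximum within each orthologue group. The per-target
framing matters at fixture scale — a small scaffold bank re-uses
structures across targets, and a global comparison would saturate at 1.

## Fingerprints and similarity

Fingerprints are extended-connectivity fingerprints of radius 2 bonds
(ECFP_4) computed natively by Open Babel and folded from 4096 to 2048
bits by OR-ing the two halves. Folding collisions between distinct
substructures are inherent to fixed-width fingerprints and accepted;
the tests assert determinism and canonicality (identical structures in
any atom order give identical bits), not collision-freedom. The
Tanimoto coefficient is `|A∧B| / |A∨B|` on the bit sets; two all-zero
fingerprints are defined as similarity 1 with a warning — a degenerate
case the structure filter removes from real chemistry anyway.

## Putative inactives by sphere exclusion

Experimentally confirmed inactives are scarce for most targets, so
training sets are topped up to a 1:100 active:inactive ratio
(`sampling_config()$ratio`) with *putative* inactives: pool compounds
whose nearest-neighbour similarity to every active is below the
exclusion radius. The default radius of Tc 0.424 is the published 95%
NN-similarity radius of ChEMBL actives at human targets — inside it a
pool compound has an appreciable prior of sharing activity, outside it
the inactivity assumption is defensible. It is a configuration knob,
not a constant. Measured inactives are used first; the sampler draws a
seeded uniform shuffle of the eligible pool, is deterministic given the
seed, and never exceeds `ratio · n_actives`. No mutual-dissimilarity
constraint is imposed among the sampled compounds; the published
protocol is ambiguous on this point and the uniform draw is the simpler,
reproducible choice.

## Models and calibration

Three classifier families are supported with the benchmarked
hyper-parameter grid (`hyperparameter_grid()`): random forests of 5, 50
or 500 trees (`mtry = floor(sqrt(p))`, unlimited depth), Bernoulli
naive Bayes with Laplace smoothing α of 1.0 or 0.1 (implemented as
closed-form matrix algebra over the binary fingerprint — the natural
generative model for bit vectors), and linear-kernel SVMs with cost
0.01, 1 or 100. Class weighting is on by default and balances the two
classes by inverse frequency, compensating the deliberate 1:100
imbalance; for the generative naive Bayes the equivalent is equal class
priors.

Raw classifier scores are not probabilities, so every model is wrapped
in Platt scaling: a sigmoid `p = 1/(1 + exp(A·s + B))` fitted by
maximum likelihood with Platt's smoothed targets `(n₊+1)/(n₊+2)` and
`1/(n₋+2)`, which guard against overconfidence on small calibration
sets. Calibration uses the two-fold ensemble contract: the training
data is split into two stratified halves (stratification keeps both
classes in both halves; the folds are seeded and reproducible), the
classifier is fitted on each half with the sigmoid fitted on the
held-out half, and predictions average the two calibrated
probabilities. Within each member the sigmoid is monotone (A ≤ 0 for
activity-oriented scores), so calibration never reorders compounds
within a member; the two-member average can in principle swap
near-ties, which the tests bound by rank correlation. Models
serialize to a bundle directory (JSON manifest plus state) and
round-trip bit-stably.

## Evaluation

Cross-validation uses an expanding chronological window: with
`t = floor(n/(n_splits+1))` and 5 splits, the test blocks are the five
consecutive windows of size `t` ending at the newest record, and each
fold trains on everything strictly older. Every test compound is newer
than all of its training compounds, emulating prospective prediction;
records without dates sort last. Metrics at the p > 0.5 decision
threshold are precision (undefined, not zero, when nothing is called
active), recall and F1; ranking quality is PR-AUC (interpolation-free
step summation with tied scores grouped) and BEDROC with α = 20, the
Truchon–Bayly early-recognition measure that exponentially rewards
actives near the top of the ranking. BEDROC's implementation is tested
at its analytic extremes (1 and 0 within 0.01), for invariance under
monotone score transforms, and for small-α linearity in the mean
active rank.

The benchmark pairs two arms per target over *identical* folds and
seeds: the base arm trains on human actives plus the shared inactive
set; the augmented arm additionally receives orthologue actives
strictly older than each fold's test block. Sampled inactives carry no
assay dates and inherit dates interleaved through the target's active
chronology, keeping each fold's class mix representative. Negatives
are sampled once per target and shared by both arms, so paired deltas
are attributable to the added actives; per-fold re-sampling would
confound the comparison with sampling noise. Summaries report
per-target paired deltas, the share of targets with stable-or-improved
F1, and medians with interquartile ranges (the spread statistic is the
IQR; fold aggregation is the fold mean per target).

## The synthetic study

`fixture_spec()` defines a fully synthetic study so that every module
runs and is tested without database downloads. The library enumerates
eight drug-like scaffolds (benzanilides, sulfonanilides,
benzimidazoles, diaroylpiperazines, diaryl ethers, benzoates,
arylpyridines, benzylamides) with twelve common substituents; scaffold
membership is the cluster label, and intra-cluster fingerprint
similarity exceeds inter-cluster similarity on average. All generated
structures pass the curation filter by construction.

Defaults were chosen once to mirror the magnitudes reported for the
public repositories: a 1.1% orthologue conflict rate; paired affinities
differing by a zero-mean Gaussian of 0.75 pChEMBL units, which implies
a median absolute discordance of `0.75 · qnorm(0.75) ≈ 0.51` and a
both-active fraction near 95% when actives are drawn around pChEMBL
6.4 ± 0.8; 12 targets with 40 human and 15 orthologue actives each, of
which 2 targets are human-sparse and only become modellable through
orthologue additions. Orthologue chemistry occupies a scaffold absent
from each target's human training clusters; for every other target a
fraction of the *newest* human actives is drawn from that same novel
scaffold, so chronological test windows contain chemistry that
orthologue training data can explain — the mechanism by which
orthologue inclusion improves the augmented arm — while the remaining
targets keep orthologue space fully disjoint, which is what the NN
audit measures. Affinities are generated directly on the pChEMBL scale
and emitted as nM standard values; the unit-conversion path is tested
separately with explicit inputs.

What passing on fixtures does *not* show: real SAR landscapes are not
smooth functions of scaffold membership, real assay noise is not
Gaussian and homoscedastic, real date fields cluster by publication,
and the fixture's scaffold bank is far smaller than pharmaceutical
chemical space. The fixtures validate the *machinery* — bookkeeping,
determinism, threshold arithmetic, statistical summarizers, fold
chronology — not the biological claim itself.

## Numerical choices and degenerate inputs

* Tie-breaks are everywhere deterministic: largest-fragment selection
  falls back to lexicographic canonical-SMILES order; duplicate
  collapse keeps the earliest date, then original row order; BEDROC
  breaks tied scores by stable input order with a warning.
* Platt fitting minimises the smoothed negative log-likelihood with
  BFGS from `(A, B) = (0, log((n₋+1)/(n₊+1)))`, using the
  `log1p(exp(·))` form guarded against overflow.
* Single-class inputs error with the missing class named (training,
  calibration folds, PR-AUC, BEDROC); an all-active ranking is the one
  degenerate BEDROC case defined as 1, with a warning.
* Groups below the minimum size report `NA` rather than 0 (concordance
  groups < 3 pairs, undefined precision, singleton NN groups).
* All randomness flows through explicit integer seeds (fixture
  generation, calibration splits, forest growth, negative sampling);
  there is no reliance on global RNG state, and fixed seeds reproduce
  results byte-identically.

## Problem sizes

The shipped test suite and the acceptance script run the pipeline at
fixture scale — hundreds of compounds, a dozen targets, three of the
eight grid settings in the scripted benchmark (random forest with 50
trees, naive Bayes with α = 0.1, SVM with C = 100) — sizes chosen so
the whole suite completes in about a minute on one core while still
exercising every stage at realistic class imbalance. The full grid and
larger studies run through the same exported functions by passing a
larger `fixture_spec()` or real curated tables.

## Known limitations

* Open Babel's ECFP_4 bit assignment differs from other toolkits'
  Morgan implementations; fingerprints are internally consistent but
  not bit-compatible with externally computed ones.
* No tautomer canonicalisation (see above).
* The conflict audit's exact-SMILES identity is deliberately strict;
  near-duplicates (salts that standardised differently, stereoisomers)
  are not matched.
* Orthologue merging is flat: all species are weighted equally, and the
  protein-change ratio is reported but not used to filter mappings.
* The external-validation harness scores any labelled table but ships
  with no external data; the proprietary datasets used in the original
  benchmarking exercise are not reproducible here.
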