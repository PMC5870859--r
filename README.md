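# orthotarget

Orthologue-aware ligand-based target prediction in R.

*In silico* target deconvolution trains one classifier per protein on the
fingerprints of its known ligands, then scores new compounds across all
targets to propose a mode of action. Restricting training data to one
species throws away the measurements made on **orthologues** — the
closest relatives of a gene in other species, which usually conserve
function and ligand preferences. `orthotarget` implements the complete
workflow for auditing and exploiting cross-species bioactivity:

* **Curation** of ChEMBL-style activity and PubChem-style inactivity
  tables: pChEMBL ≥ 5 (10 µM) or declared-active comments, assay
  confidence > 5, structure standardization (largest fragment,
  neutralization, canonical SMILES), and drug-likeness filters (carbon
  required, MW 100–1000 Da, no atoms with Z in 21–32, 36–52 or ≥ 54).
* **Orthologue mapping** through HomoloGene-style homology groups, with
  duplicate-SMILES removal, a 10-active minimum per modelled target, and
  reporting of targets only modellable thanks to orthologue data.
* **Audits**: bidirectional active/inactive conflict analysis with
  per-mapping counts and a compatibility percentage; human–orthologue
  pChEMBL concordance (R², median |Δ|, both-active fraction);
  discordance binned by the homology protein-change ratio;
  nearest-neighbour ECFP_4 Tanimoto chemical-space comparisons.
* **Negative sampling** by sphere exclusion: putative inactives drawn
  from a pool at a 1:100 active:inactive ratio, excluding anything
  within Tc 0.424 of an active.
* **Models**: per-target random forest, Bernoulli naive Bayes and
  linear-SVM classifiers on 2048-bit ECFP_4 fingerprints with balanced
  class weights and two-fold Platt calibration, so predictions are
  probabilities `p(activity) ∈ [0, 1]`.
* **Evaluation**: five-fold expanding-window time-series
  cross-validation with precision/recall/F1 at p > 0.5, PR-AUC and
  BEDROC (α = 20, the Truchon–Bayly early-recognition metric
  `RIE · Ra·sinh(α/2)/(cosh(α/2) − cosh(α/2 − α·Ra)) +
  1/(1 − e^{α(1−Ra)})`), paired before/after-orthologue benchmarking,
  and an external-validation harness.
* **Fixtures**: a deterministic generator of scaffold-clustered compound
  libraries and synthetic ChEMBL/PubChem/HomoloGene-style tables with
  controllable conflict rate and concordance noise, so the entire
  pipeline builds and tests without any database download.

Structure handling (parsing, canonical SMILES, descriptors, native
ECFP_4) is delegated to [Open Babel](https://openbabel.org) through the
`obabel` executable, which must be on `PATH`.

## Worked example

Build the synthetic study end to end and benchmark orthologue inclusion:

```r
library(orthotarget)

spec   <- fixture_spec(seed = 42)             # 12 targets, 800 compounds
tables <- generate_bioactivity_tables(spec)
build  <- build_pipeline(tables, sampling = sampling_config(seed = 43))
print(build)
#> Orthologue-aware training-set build
#>   structures                 distinct=800, rejected=0
#>   structure_filter           checked=800, failed=0
#>   actives                    input=592, selected=574, rejected=18
#>   inactives                  input=61, distinct=61
#>   label_conflicts_resolved   =0
#>   targets                    before_orthologues=10, after_orthologues=12, newly_enabled=2
#>   modelled targets: 12 (2 newly enabled by orthologues)

print(build$audits$conflicts_fwd)
#> Orthologue bioactivity conflict report (orthologue actives vs human inactives)
#>   mapped bioactivities : 162
#>   conflicting          : 1 (0.62%)
#>   compatibility        : 99.38%
#>   target pairs         : 12 (11 conflict-free, 91.7%)

print(build$audits$concordance)
#> Human / orthologue affinity concordance
#>   pairs                  : 112
#>   overall R-squared      : 0.573
#>   median |delta pChEMBL| : 0.42
#>   both active (>= 5.0)  : 102 (91%)

bm <- run_benchmark(build, grid = hyperparameter_grid()[8, ], seed = 44)
print(bm$table, digits = 3)
#>    algorithm hyperparameter f1_before f1_after median_f1_delta
#> 1 linear_svm       cost=100     0.809    0.933           0.133
#>   share_stable_or_improved bedroc_before bedroc_after
#> 1                        1         0.997            1
```

Reading the numbers: of 592 raw activity records, 574 survive curation;
two targets only reach the 10-active minimum because of orthologue
additions ("newly enabled"). Only 1 of 162 mapped orthologue actives is
annotated inactive at its human partner (99.4% compatible), paired
affinities correlate with R² 0.57 and a median discordance of 0.42
pChEMBL units, and 38% of orthologue actives have no human neighbour
above Tc 0.4 — dissimilar chemistry that, once merged, lifts the
median time-split F1 of the C = 100 linear SVM from 0.81 to 0.93 with
every target stable or improved.

Individual stages are exported (`standardize_structures`,
`select_actives`, `merge_orthologue_actives`, `conflict_analysis`,
`concordance_analysis`, `sphere_exclusion_sample`, `fingerprint`,
`target_model`, `cv_target`, `benchmark`, …), and a thin command-line
wrapper with `make-fixtures` / `build` / `sample-negatives` /
`benchmark` subcommands ships at `inst/cli/orthotarget.R`.

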