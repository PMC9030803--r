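# splicefactoR

Predicting the splicing-regulatory activities of RNA-binding proteins
(RBPs) from their amino-acid sequences and predicted one-dimensional
structural profiles.

Trans-acting splicing factors modulate alternative splicing by binding
cis-elements in pre-mRNA, and their activity — expressed as
log10(fold change in splicing outcome) — has been measured experimentally
for only a small number of protein domains. `splicefactoR` implements a
sequence-to-activity regression pipeline for this setting (tens of
labelled proteins, hundreds of candidate descriptors) and a synthetic
cohort generator with planted signal so that every stage of the pipeline
can be exercised and validated without any external data.

## The method

Each protein is encoded as a fixed 700-dimensional vector:

| block | features |
|---|---|
| amino-acid composition (AAC) | 20 |
| dipeptide composition (Dual-AAC), `D_ij = f_ij / (L-1)` | 400 |
| CTD physicochemical descriptors, 21 per property (hydrophobicity, normalized Van der Waals volume, polarity, polarizability) | 84 |
| 3-state secondary structure: composition + dual composition + distribution (27) and class-probability third-means (9) | 36 |
| 8-state secondary structure: likewise (112 + 24) | 136 |
| third-means of ASA, HSE up/down, contact number, backbone angles θ, τ, φ, ψ | 24 |
| **total** | **700** |

Near-zero and constant columns are removed and the survivors z-scored,
`X' = (X − X̄)/sd(X)`. Features are then ranked by minimum-redundancy–
maximum-relevance (mRMR; 3-state discretization at mean ± 0.5 sd, plug-in
mutual information, difference scheme), and a greedy forward search
wrapped around partial least squares regression (PLSR, NIPALS, 3
components by default) grows a subset from the first two mRMR features,
adding at each step the feature maximizing the mean held-out Spearman
rank correlation under 5-fold cross-validation. Models are scored with
five metrics: R² (explained-variance form
`Σ(ŷ−ȳ)²/Σ(y−ȳ)²` by default, the standard `1−SSE/SST` form is one flag
away), RMSE, NRMSE (RMSE / sd of observations), Pearson's ρ, and
Spearman's γ (`1 − 6Σd²/(N(N²−1))` when ranks are tie-free). Grid-searched
random-forest and RBF-SVM regressors are available as baselines.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic cohort (85 proteins, activities planted on `Dual-AAC_GT`,
`Hydrophobicity_distribution_H-0.0` and `ASA-2th` with weights
1 / 0.8 / 0.6 plus Gaussian noise):

```sh
Rscript analysis/01_simulate.R    # cohort -> FASTA + TSV + profile dir
Rscript analysis/02_featurize.R   # 700-column matrix, filter, z-score
Rscript analysis/03_select.R      # mRMR lists, forward search, 13-block curve
Rscript analysis/04_evaluate.R    # sweep, CV, family importance, baselines
```

A run with the committed seeds prints:

```
cohort: 85 proteins, lengths 62-487
feature matrix: 85 x 700 raw -> 699 after filtering
forward search: best CV Spearman 0.993 at 8 features
selected head: Dual-AAC_GT, Dual-AAC_TS, Hydrophobicity_distribution_H-0.0,
               ASA-2th, ...
CV Spearman: full matrix 0.271, best 8-feature subset 0.993
family Spearman: sequence 0.610, physicochemical 0.298, structural 0.155
baselines (best subset): RFR 0.903, SVMR 0.978 vs PLSR 0.993
```

Reading: with only 85 samples the full 699-column model generalizes
poorly (CV Spearman 0.27), the combined mRMR + forward search recovers
all three planted features within its first four selections and reaches
CV Spearman 0.99, and the family decomposition correctly attributes most
of the signal to the family holding the largest planted weight. The same
functions accept real data: a FASTA file, an `id<TAB>activity` table, and
one structural-profile TSV per protein (see `?read_structural_profile`
for the column dialect and the `column_map` adapter for real
predictor outputs).

In R, the pipeline is one call:

```r
library(splicefactoR)
d <- simulate_dataset(simulation_spec(rng_seed = 1))
res <- run_activity_pipeline(d$proteins, d$profiles,
                             run_config(max_forward_features = 10))
res$manifest$best_forward_spearman
```

## Scope

The package parses/emulates structure-predictor output; it never runs a
structure predictor itself, and the synthetic generator does not attempt
to mimic real RBP domain grammar (SR repeats and the like) beyond an
optional residue-composition bias. See the methods vignette
(`vignettes/activity-prediction-methods.Rmd`) for modelling assumptions,
parameter choices and limitations.
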