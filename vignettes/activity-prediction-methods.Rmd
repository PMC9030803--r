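---
title: "Methods: predicting splicing-factor activity from sequence and predicted structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting splicing-factor activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicefactoR)
```

## The problem

Splicing factors are RNA-binding proteins (RBPs) whose regulatory
activity — the log10 fold change in a splicing outcome when the protein
is recruited to a reporter — has been measured for only a few dozen
domains. The regression problem is therefore extreme: tens of labelled
samples against hundreds of sequence-derived descriptors, most of them
collinear. `splicefactoR` implements the full modelling stack for this
setting and, because the experimental cohorts are not redistributable, a
synthetic generator whose planted signal makes every stage falsifiable.

## The encoding

Every protein is mapped to a fixed 700-feature vector; the schema
(`feature_schema()`) is the contract shared by the encoders, the
selection stages and the generator.

* **AAC (20)** — residue frequencies, `p_i = c_i / L`.
* **Dual-AAC (400)** — ordered adjacent-pair (dipeptide) frequencies with
  denominator `L − 1`, i.e. the composition of 0-spaced residue pairs.
* **CTD (84)** — for each of four properties (hydrophobicity, normalized
  Van der Waals volume, polarity, polarizability) the sequence is recoded
  into three groups tagged P/N/H and summarized by 3 composition, 3
  transition and 15 distribution features. The groupings are the
  canonical Dubchak-style tables from the CTD literature; they are
  configurable via a TSV (`ctd_groupings(path)`) because published
  variants differ in detail. Distribution uses five anchors per symbol —
  the first occurrence plus the 25/50/75/100% occurrence quantiles,
  occurrence index `max(1, ceiling(q * n_g))` — which is what the
  21-per-property budget (3 + 3 + 15) forces; a symbol absent from the
  sequence contributes five zeros.
* **SS3/SS8 (36 + 136)** — the 3- and 8-state secondary-structure label
  sequences are treated as pseudosequences and summarized by the same
  composition / dual-composition / distribution machinery (27 and 112
  features), plus three-part means of each class-probability track
  (9 and 24). The 8-to-3 condensation is fixed: G/H/I → H, B/E → E,
  everything else → C, and the profile reader rejects files that violate
  it.
* **Other tracks (24)** — three-part means of ASA, HSE-up, HSE-down,
  contact number and the four backbone angles. Part boundaries sit at
  `floor(L/3)` and `floor(2L/3)`; proteins shorter than 3 residues are
  rejected rather than padded. Angles are averaged as plain degrees — no
  circular mean — which is a documented limitation: a track oscillating
  around ±180° averages toward 0°.

## Normalization and filtering

Columns whose maximum absolute value is below `1e-8` are removed, as are
constant columns (z-scoring is undefined for them); the survivors are
z-scored with the sample standard deviation (denominator n − 1). The
stored center/scale vectors invert the transform exactly. Normalization
statistics are computed on the full cohort before cross-validation —
matching the workflow this pipeline models, where scaling precedes fold
splitting — so held-out metrics are mildly optimistic; with tens of
samples this choice is visible but small, and per-fold scaling can be
layered on by callers that need strict leakage control.

## Feature selection

**mRMR.** Features and target are discretized into three states (below /
within / above a mean ± 0.5 sd band — on z-scored input the thresholds
are exactly ∓0.5) and scored by plug-in mutual information in nats. The
maxRel list sorts by relevance alone; the mRMR list is greedy, each step
maximizing relevance minus the mean MI with already-selected features
(the difference scheme; the quotient scheme is selectable). Ties break by
ascending candidate position, making the ranking deterministic. The
band width and scheme are configurable because the upstream discrete-mRMR
protocol this follows does not pin them down.

**Forward search.** Starting from the first two mRMR features (a
3-component PLSR needs at least three predictors, so scoring begins at
the first addition), every remaining candidate is scored by the mean
held-out Spearman correlation of a PLSR on the augmented subset, and the
argmax is appended. The fold assignment is drawn once per run and shared
by every candidate evaluation — otherwise the argmax is driven by fold
noise rather than by the features. The candidate pool can be restricted
to the head of the mRMR list (`pool_size`); the recovery experiments use
the top 100, which is the combined filter-then-wrapper protocol at a
practical cost.

## The regression model and metrics

PLSR is fitted by NIPALS (inner tolerance 1e-10, at most 500 iterations
per component; with a single response the loop converges immediately).
Requesting more components than the residual X-rank supports stops
extraction early with a warning. With as many components as features on
a full-rank design, PLSR equals ordinary least squares — one of the
oracle checks in the test suite (tolerance 1e-6 against `lm()`).

Five metrics are reported per fold and averaged arithmetically over the
five folds. R² defaults to the explained-variance form
`Σ(ŷ−ȳ_obs)²/Σ(y−ȳ_obs)²`, which can exceed 1 for a biased predictor;
the standard `1 − SSE/SST` form is always reported alongside
(`r2_alt`) and can be made primary via `r2_form`. The two coincide for an
OLS fit evaluated on its training data. Spearman's γ uses the closed
form `1 − 6Σd²/(N(N²−1))` when ranks are tie-free and midrank Pearson
otherwise (they coincide without ties, an identity tested to 1e-12). A
constant prediction vector carries no ranking information and scores 0
by convention rather than erroring inside selection loops.

Cross-validation splits a seeded permutation into near-equal folds,
distributing remainders one per fold from the front; an 85-sample cohort
under 5 folds yields validation folds of exactly 17.

## The synthetic generator

`simulation_spec()` fixes the study conditions:

* **Cohort** — 85 proteins by default (the size of the experimental
  cohort this emulates), lengths uniform on 50–500, residues i.i.d.
  (optionally composition-biased).
* **Profiles** — an 8-state secondary-structure label per residue from a
  persistent Markov chain (stay probability 0.85, jumps drawn from
  DSSP-like stationary frequencies), the 3-state label by condensation,
  and probability tracks from a Dirichlet with concentration 20 on the
  drawn label and 1 elsewhere, so the argmax matches the label in ≥ 95%
  of rows while staying realistically soft. ASA is Beta-distributed on
  [0, 250] Å²; exposures and contact numbers are Poisson counts; angles
  are normal/uniform draws wrapped into (−180°, 180°].
* **Activities** — a sparse linear function of *encoded* features:
  the planted columns are z-scored across the cohort and combined with
  fixed weights plus Gaussian noise. Planting on encoded features rather
  than latent sequence rules makes recovery tests exact and independent
  of any encoder bug being symmetric between generator and pipeline.
  The default plants `Dual-AAC_GT`, `Hydrophobicity_distribution_H-0.0`
  and `ASA-2th` with weights 1 / 0.8 / 0.6 and noise sd 0.15 (about a
  tenth of the signal sd); `noise_relative = TRUE` expresses the noise
  directly as a multiple of the signal sd.

Planted features must be *identifiable*: recovery-by-name is only
meaningful for features that are not near-duplicates of other schema
columns. Dual-pair features of a persistent-state track fail this —
`SS8_Dual_GG` is essentially collinear with `SS8_composition_G` under
this generator — which is why the default structural exemplar is a
track summary (`ASA-2th`) whose maximum absolute correlation with any
other feature is ≈ 0.26. The generator emulates label-consistent tracks
and realistic ranges, not real RBP biology: no low-complexity/SR-repeat
grammar, no length–structure coupling, no correlated physicochemical
composition. Passing recovery tests therefore demonstrates that the
pipeline's machinery is correct and self-consistent, not that real
activities are predictable at these accuracies.

## Problem sizes used by tests and scripts

The suite works at three scales, chosen as the smallest that make each
property visible: desk-scale fixtures for exact values; n = 80–120
cohorts for curve shapes (a 3-latent-factor design whose component sweep
peaks near 3; a forward trace that rises and then declines past the
planted support); and n = 200 cohorts, 10 seeds, for the recovery
experiment (all planted features surfaced within |planted| + 5
selections in ≥ 8/10 seeds with held-out Spearman ≥ 0.9). The
acceptance script repeats the recovery experiment at 5 seeds derived
from its `--seed` argument. Baseline grids default to the full printed
parameter spaces (trees 1–99 × mtry 1–29; C over 8 values × Γ over
2⁻⁶…2⁶); drivers and tests pass reduced grids, which is a runtime
choice, not a different protocol.

## Known limitations

* No circular statistics for angle tracks (above).
* Mutual information uses a fixed 3-state discretization; very skewed
  features lose resolution.
* Greedy selection offers no optimality guarantee beyond the per-step
  argmax, and with heavily aliased features it may return a proxy of the
  causal feature — by design of greedy wrappers, not an implementation
  defect.
* Cohort-level normalization before CV (above).
* The explained-variance R² is kept as the primary form for comparability
  with the modelling tradition this package follows, despite its known
  bias; readers wanting the standard form should use `r2_alt`.
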