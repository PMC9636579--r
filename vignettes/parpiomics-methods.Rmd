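---
title: "Models and methods behind parpiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind parpiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parpiomics)
library(dplyr)
```

parpiomics implements an integrated analysis of how ovarian cancer cells
respond to PARP inhibitors (PARPi), built around a pair of *BRCA1*-isogenic
cell lines: a *BRCA1*-null, PARPi-sensitive line (UWB) and its
BRCA1-reconstituted, PARPi-insensitive derivative (UWB+B). Four data types
flow through the package: competitive chemical-proteomics pulldowns that
identify the proteins a drug-derivatized bead actually binds; TMT 6-plex
phosphoproteomics and label-free ADP-ribosylome profiling that measure
signaling responses to rucaparib; gene-set over-representation analysis that
interprets the resulting hit lists; and viability grids that quantify
drug-combination synergy. Each stage is specified as a tibble-in/tibble-out
function, and a seeded simulator with planted ground truth exists for every
input type, so the complete workflow runs and is validated at desk scale.

This vignette records the models, the tunable parameters with their
defaults, the numerical conventions, and the design decisions that were
genuinely open.

## Quality control of quantification tables

MaxQuant-style tables are read by `read_quant_table()`, which discovers
intensity columns by header prefix (`"iBAQ "`, `"Reporter intensity
corrected "`, or `"Intensity "` depending on dialect) because MaxQuant
dialects drift across versions; the prefix is an argument for anything
non-standard. `qc_filter()` then removes reverse (decoy) hits, common
contaminants, identifications with posterior error probability
`pep >= 0.05`, and features with no intensity in any sample. For the
removal report each feature is counted once, at the first rule it violates,
under the fixed precedence reverse → contaminant → PEP → zero-intensity.
The precedence is a reporting convention only: the surviving set is the
same under any order.

Zero intensities are kept as zeros by the parser and interpreted as
*missing* by the downstream pipelines (`zero_as_missing = TRUE`
throughout): in intensity-based proteomics a stored zero means "not
detected", not "absent at zero abundance". Features observed in at least
one sample are retained and their gaps are imputed.

## Imputation, transformation, tests

`impute_column_min()` replaces each missing cell with the smallest present
value of its own column — the standard left-censoring imputation, justified
when missingness is concentrated at the detection limit. It runs before
`log2_transform()`, which rejects non-positive cells so a skipped
imputation is caught immediately, and transformation precedes testing.

Two-sample comparisons use the pooled-variance Student *t* by default
(`variant = "welch"` available). Degenerate inputs follow fixed
conventions: two constant equal groups give `p = 1`, two constant unequal
groups give `p = 0`. The TMT phospho contrast instead uses a one-sample
Student *t* of the replicate-wise treated − vehicle log2 ratios against
zero, because TMT channels pair within a replicate and the ratio is the
natural replicate-level observation. Multiple testing is controlled by
Benjamini–Hochberg throughout.

## The adaptive fold-change threshold

Phosphosite calls use a data-driven cutoff: twice the average per-replicate
spread of the log2 ratios (`adaptive_sd_threshold()`, `multiplier = 2`).
Two choices here were open:

* **Averaging axis.** The spread is estimated per replicate column across
  features and then averaged (`average = "per_replicate"`, the default);
  the alternative reading — per-feature spread across replicates, then
  averaged — is available as `average = "per_feature"`.
* **Spread estimator.** The default estimator is the normal-consistent MAD
  rather than the classical standard deviation. The threshold is meant to
  capture the spread of *unregulated* measurements, but the classical SD is
  inflated by exactly the regulated tail the threshold is supposed to
  detect: with 2% of sites truly shifted by |log2FC| = 1.5 over a null
  spread of 0.25, the classical SD rises to ≈ 0.33 and the threshold to
  ≈ 0.66, while the MAD stays at the null 0.25 (threshold ≈ 0.5).
  `estimator = "sd"` restores the classical estimator.

The fold-change gate is strict (`|log2fc| > threshold`); the ADP-ribosylome
gate is inclusive at its stated raw fold change (`|log2fc| >= log2(2)`).
Both conventions are asserted in the test suite.

## Rank-invariant (iterative rank-order) normalization

`iron_normalize()` scales every reporter-ion channel onto a common
reference using only a *rank-invariant* feature set, so that regulated
features do not drag the normalization. The contract:

1. `reference = "auto"` picks the column whose within-column ranks are
   closest (summed absolute rank displacement) to the pseudo-reference
   formed by each feature's median rank. Using ranks rather than values
   makes the choice — and hence the whole procedure — exactly invariant to
   rescaling any single channel.
2. The invariant set starts as all features. Each iteration fits a
   monotone mapping of each column onto the reference over the invariant
   set (quantile mapping between sorted invariant values, linearly
   interpolated, ratio-extrapolated beyond the observed range), applies
   it, and removes the most displaced `trim = 5%` of invariant features
   whose residual |log2 ratio| still exceeds `stab_tol = 0.01`.
3. Iteration stops when the invariant set is self-consistent or after
   `max_iter = 10` rounds; each column is finally centered so its median
   log-ratio to the reference over the invariant set is exactly zero.

Consequences asserted by tests: the reference column is never altered; a
pure 2× shift is undone to within 10⁻⁶; planted 8-fold outliers are
expelled from the invariant set while unperturbed features are restored to
within 2%; a second pass returns scale factors of 1.

## Chemical-proteomics scoring

In a competition pulldown, lysate preincubated with free drug (CT)
scavenges true targets, so specific binders are enriched in the pulldown
(PD) relative to CT. `score_competition()` calls a protein *specific* when
its mean log2(PD) − log2(CT) exceeds 1.5 — note: a log2-scale cutoff, i.e.
≈ 2.8-fold raw — with Student *t* `p < 0.05` across replicates.

Cross-line comparison uses riBAQ (iBAQ divided by the sample's total
iBAQ), computed per pulldown replicate so the replicate structure survives
into the *t* test. The line gate is deliberately on the *raw* riBAQ ratio
(> 1.5 or < 1/1.5, with `p < 0.1`): the two gates of this module live on
different scales by design, matching how each criterion is defined.
Features absent from one line have their riBAQ imputed with the minimum
present riBAQ of that sample, mirroring the column-minimum convention.
Whether the *t* test should run on raw or log2 riBAQ was open; raw is the
default with `log_scale = TRUE` as the switch. Because riBAQ is a
within-sample proportion, it must be computed on the *full* sample before
any subsetting — subsetting first changes the denominator and manufactures
compositional artifacts.

## Over-representation analysis

`ora_test()` is a local, one-sided hypergeometric test against GMT-derived
collections: with universe size `N`, set size `K`, query size `n` and
overlap `k`, `p = P(X ≥ k)`. The enrichment factor is `(k/n)/(K/N)`, and
`filter_terms()` applies the gates overlap ≥ 3, `p < 0.01`, enrichment
≥ 1.5. The recommended universe is the set of genes *detected* in the
experiment the query came from, not the genome: testing against the
detected proteome avoids detection bias. BH is the documented
multiple-testing choice within a collection. `integrate_omics_lists()`
unions the phospho and ADPr hit lists with source flags; the union is the
query for the integrated analysis. Term-level reproduction of any specific
public annotation release is out of scope — collections are user-supplied
GMT files.

## Dose-response and Bliss synergy

Viability is normalized to the mean of vehicle wells, and Bliss
calculations run on the fraction affected `fa = 1 − viability`, clipped
into [0, 1] (clipping is counted and reported): Bliss independence is
defined on effect probabilities, so the scale is fixed here by
construction. The single-agent model is the four-parameter logistic
`y = bottom + (top − bottom)/(1 + (x/IC50)^hill)` fitted by
Levenberg–Marquardt least squares on per-concentration means under the
constraints `0 ≤ bottom ≤ top ≤ 1.2`, `IC50 > 0`, from a multi-start grid
(IC50 across the observed concentration range × hill ∈ {0.5, 1, 2});
the best-residual start wins and the reported IC50 is the relative IC50
(curve inflection). A response flat to within 0.05 carries no dose
information and is flagged non-convergent rather than fitted.

`synergy_grid()` computes `fa_expected = fa_a + fa_b − fa_a·fa_b` from the
*observed* (not fitted) single-agent means and `Δ = fa_obs − fa_expected`
per cell; positive Δ is synergy. Aggregation is mean-then-Δ: replicate
means enter the Bliss formula, with the per-cell SEM carried alongside for
a null band. Whether the original analysis used per-replicate or mean
marginals was not recoverable; mean is the default.

## The synthetic-data generators

Every generator is a pure function of its arguments including the seed
(`withr::with_seed`), and its defaults are the study's design sizes: three
biological replicates for the proteomics experiments, TMT 6-plex as three
treated/vehicle channel pairs, four biological replicates and the dose grid
0.016–10 µM for viability.

* `sim_chemprot()` — 2000 protein groups, baseline log2 iBAQ ~ N(20, 3);
  20 specific binders attenuated 2³-fold in CT; 20 additional binders also
  enriched 4-fold (riBAQ scale) in line A; cell-level log-normal noise of
  SD 0.25 log2 units. Planted binders draw their baselines from the upper
  half of the background distribution, because the affinity pulldown
  concentrates true targets in the eluate — a binder below the detection
  limit is not a recoverable target for any scorer.
* `sim_phospho_tmt()` — 5000 sites, 50 up and 50 down at |log2FC| = 1.5.
  `noise_sd = 0.25` is defined as the SD of the replicate-wise log2 ratio
  (each channel receives noise of SD 0.25/√2), so the adaptive threshold
  under the defaults sits at ≈ 0.5. Channels carry log2 loading shifts of
  SD 0.3 that the normalization must remove. Mass errors are uniform on
  ±2 ppm with 2% planted outliers beyond ±3 ppm to exercise the gate.
* `sim_adpr()` — 3000 proteins, 60 hits at raw fold change 4 (down under
  drug by default), noise SD 0.3.
* `sim_viability()` — 4PL single agents (bottom 0, top 1) plus a
  combination grid generated under exact Bliss independence with an
  optional planted Δ offset, clipped into [0, 1]; the ground truth records
  which cells took the offset unclipped.

**Missingness model.** About 5% of cells per column in the label-free
generators are set missing by intensity-dependent left-censoring: the
missingness probability decays logistically with log2 intensity (steepness
0.3 log2 units), calibrated per column to the target rate. This is the
mechanism that makes column-minimum imputation meaningful, and it is how
MS dropout predominantly arises. Missingness completely at random would
instead plant the column minimum into otherwise well-measured features,
creating artifactual fold changes that no downstream statistic can undo —
under that regime the planted-recovery properties of this workflow are
unattainable by construction. TMT reporter intensities are generated
without dropout, reflecting the near-complete within-plex quantification
of labeled peptides.

What the simulations do *not* model: peptide-to-protein inference, ratio
compression from TMT co-isolation, correlated (batch) noise, and real
biological pathway structure. Passing the recovery tests therefore
demonstrates that the statistics and gates are implemented correctly and
are well calibrated under the stated noise model — not that the pipeline
is robust to every pathology of real MS data.

## Problem sizes and determinism

The test suite exercises reduced configurations (hundreds of features) for
unit-level checks and the full design sizes (2000 features, 5000 sites,
3000 proteins, 5 × 5 dose grids) for the end-to-end recovery checks; the
whole suite runs in well under a minute. All randomness is seeded, and
`scripts/acceptance.R` derives every seed from its single `--seed`
argument.

## Known limitations

* The IRON-style normalization is implemented at the contract level
  (rank-invariant set, monotone per-column mapping, median-log-ratio-zero
  postcondition); trim fraction, iteration cap and the piecewise-linear
  mapping form are this package's choices, all exposed as arguments.
* The hypergeometric ORA replaces web-service enrichment tools; results
  depend entirely on the GMT collections supplied by the user.
* No moderated-variance (empirical Bayes) tests: with three replicates a
  moderated test would gain power, but the plain Student *t* is what the
  workflow specifies.
* FDR re-estimation of MaxQuant identifications is out of scope; the
  package honors the decoy/contaminant flags it is given.

## Worked micro-example

```{r example}
sim <- sim_chemprot(n_features = 300, n_specific = 8, n_line_diff = 0,
                    seed = 20)
calls <- score_competition(sim$line_a)
calls |>
  filter(specific) |>
  arrange(desc(log2fc_pd_ct)) |>
  select(feature_id, log2fc_pd_ct, p_pd_ct) |>
  head()
sum(calls$specific & calls$feature_id %in% sim$truth$specific_binders)
```
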