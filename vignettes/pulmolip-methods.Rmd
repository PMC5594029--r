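---
title: "Methods: from lipid intensities to phenotype models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from lipid intensities to phenotype models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmolip)
```

## The analysis problem

pulmolip implements the data-analysis side of a shotgun-lipidomics screen of
lung tissue: paired tumour and tumour-free alveolar biopsies, profiled by
direct-infusion mass spectrometry, quantified against spiked internal
standards, and related to histology scores and clinical covariates. The
pipeline has four analysis stages plus a simulator:

1. **Quantification** — identification filtering, internal-standard
   conversion to pmol, mol% normalization, presence filtering.
2. **Panel scoring** — selection of discriminative lipid panels and a signed
   log2 score evaluated by ROC/AUC and the Mann–Whitney U test.
3. **Unsupervised structure** — hierarchical clustering (Euclidean, complete
   linkage) and PCA.
4. **Phenotype regression** — NIPALS PLS2 of lipid predictors against
   histology and clinical responses, with patient-grouped ten-segment
   cross-validation and a Q² significance rule.
5. **Synthetic cohorts** — a generator reproducing the statistical structure
   the other stages assume, so everything is testable without patient data.

## Quantification model

Lipids are annotated at sum-composition level, `class [C:DB]` (sphingolipids
carry a `;0`/`;1` hydroxylation suffix; ether lipids are `PC-O`/`PE-O`;
free cholesterol is `FC`). sn-resolved names (`PC 16:0/16:0`) are accepted
and collapsed to sum composition, which is the resolution of the quantitative
tables.

An identification is kept when its mass error is within **2.5 ppm** and its
intensity is at least **10×** the blank-control intensity of the same
species; species without a blank entry pass the ratio test (blank = 0). Both
thresholds are arguments.

Quantification uses two rules. LPC, PC, PE, SM and TAG species convert via
their same-class internal standard, `amount = intensity / IS_intensity ×
IS_amount`. All other classes convert against the summed intensity of the
mode's designated standard set (positive: LPC, SM, PC, TAG; negative: LPC,
PC, PE): `amount = intensity / Σ IS_intensity × Σ IS_amount`. This form
preserves units and reduces to the class rule when the set has one member.
Amounts are closed to **mol%** per sample (non-missing lipids sum to 100).

Undetected lipids are *missing*, never zero. No imputation is performed:
every downstream analysis first applies a presence filter (90% for
exploratory analyses, 100% for panel selection and PLS), mirroring how such
screens restrict each analysis to consistently detected species. mol%
values are not re-closed after filtering, so log-scale statistics are
unaffected by the removal.

## Panel score

For a two-group contrast, candidate lipids (complete cases only) are tested
by a two-sided Welch t-test on log2 mol% — Welch because tumour/control
groups are unbalanced, not all patients contribute both tissues, and equal
variances are not defensible. The fold change is computed on group means of
mol% and log2-transformed. A lipid enters the panel when `p <
p_threshold` (default 0.01) and `|log2FC| > log2fc_threshold` (default 1,
i.e. twofold), strict inequalities. No multiplicity correction is applied at
the default thresholds (the selection is a fixed screening rule, not an
inference); log2 of mol% requires positivity, which the 100% presence filter
guarantees, so no pseudocount is used.

The per-sample score is

\[ S = \sum_i A_i \, c_i \]

where \(A_i = +1\) if the lipid is higher in group 1 (\(-1\) otherwise) and
\(c_i\) is the log2 mol% of lipid \(i\) centred on the *pooled cohort* mean
recorded at selection time. Pooled centring (rather than per-group) is one of
two readings of "mean centred"; it is stored in the panel object so the
alternative is swappable. Self-centred scores sum to zero, and swapping the
group labels flips every sign and negates every score.

ROC curves are threshold-free with half-credit for ties, so AUC equals
\(U/(n_1 n_2)\) with \(U\) the Mann–Whitney statistic of the favourable
direction; the orientation is chosen so AUC ≥ 0.5 and is reported. The
Mann–Whitney implementation is exact (full enumeration) for combined
\(n \le 12\) without ties and uses the tie- and continuity-corrected normal
approximation otherwise.

## Unsupervised structure

Clustering and PCA run on log2 mol% with per-lipid mean centring — the
transform is not dictated by the score construction elsewhere in the
pipeline, but using the same log2 world keeps the two views comparable; it
is configurable. Clustering is complete linkage on Euclidean distances
(`stats::hclust`), whose cophenetic distances dominate the original
distances; trees serialize to Newick with merge heights as branch lengths.
Because cluster cohesion in this field is often quoted as a correlation,
`clade_summary()` reports both the merge height and the mean pairwise
Pearson correlation within each clade — the two metrics answer different
questions and are deliberately both present. PCA is the spectral
decomposition of the covariance (optionally correlation) structure, with a
deterministic sign convention: the largest-magnitude loading of each
component is positive.

## PLS2 phenotype regression

Clinical data and histology scores are responses (Y), lipid mol% are
predictors (X). All variables are min–max scaled to [0, 1] (constant columns
map to 0 with a warning; the transform is invertible). Two-level categories
encode as 0/1; ordered multi-level scores (inflammation 0–3, emphysema 0–10,
GOLD stage with "no COPD" = 0) encode as level/max, preserving order.
Samples missing a chosen response are dropped for that model and logged.

Inside the fit, both blocks are additionally column-centred and scaled to
unit variance (both toggles exposed), matching the behaviour of the standard
PLS2 implementations. Components come from the NIPALS iteration
(`w ∝ X'u`, `t = Xw`, `c = Y't/t't`, `u = Yc/c'c`), deflating X by `t p'`
and Y by `t c'`. Numerical choices worth knowing:

- convergence is declared when successive `t` vectors agree to 1e-10
  (relative); if the iteration oscillates — which happens when the two
  leading singular values of `X'Y` nearly tie — the component is resolved
  directly as the dominant singular vector of `X'Y`, which is the NIPALS
  fixed point. Truly degenerate components (no X/Y covariance left) stop the
  extraction early with a message.
- each weight vector is sign-fixed (largest-magnitude entry positive) so
  results are reproducible across numerical libraries.
- standardized coefficients are `B = W (P'W)^{-1} C'`; with one response,
  full-rank X and all components they equal the OLS solution, which the
  tests exploit as an oracle.

The default of three components follows the practice of inspecting
\(t_1 \ldots t_3\); it is configurable. Correlation circles report the
Pearson correlation of every original variable with the chosen pair of
t-components; zero-variance variables get `NA`, not 0.

### Cross-validation and Q²

Patients — not samples — are shuffled into ten near-equal segments, so
matched tumour/control samples never straddle the train/validation split.
For each held-out segment a model on the rest predicts it, cumulatively per
component. Per response and component,

\[ Q^2_h = 1 - \mathrm{PRESS}_h / \mathrm{RSS}_{h-1}, \]

with PRESS accumulated over held-out segments and RSS taken from the
full-data model (RSS\(_0\) = sum of squares about the mean). A response is
flagged significant when **any** component reaches Q² ≥ 0.0975. The
segmentation seed is explicit everywhere.

## What the synthetic generator emulates

`cohort_config()` states the cohort the pipeline is designed for; the
defaults are the stated world, not tuning knobs:

- **Geometry**: 26 patients, 43 samples — 17 matched pairs, 6 tumour-only,
  3 control-only; 311 lipids over 11 classes with PC the dominant class.
- **Tumour effects**: TAG and CE up (+2 log2), DAG up (+1), PG down (−2),
  fully saturated PC down (−1) — the surfactant-loss signature. Because
  mol% closure redistributes mass, null lipids acquire a small apparent
  shift (≈ −0.5 log2 at these effect sizes); the twofold selection bound
  absorbs it, and the selected panels end up dominated by TAG/CE/PG exactly
  as expected.
- **Noise**: log-normal per lipid (σ = 0.3 on log2), per-lipid baselines
  spread around class means (SD 1.0), and a per-patient random intercept
  (SD 0.2) that induces within-patient correlation of matched pairs.
- **Structured missingness**: a third of lipids are always detected
  (abundant species), a tier is detected at 95% per sample, the rest at
  20–90%; TAG/CE detection is additionally suppressed in alveolar tissue and
  PG in tumours (tier-protected species excepted), reproducing
  tissue-exclusive detection. Tier fractions were derived analytically so
  ≈45% of lipids pass the 90% presence filter and ≈30% the 100% filter.
- **Covariates**: age 44–71 and emphysema grade 0–10 generated with
  correlation 0.5 and coupled through a *shared* latent to four designated
  long-chain PS/PI species (PS [38:4], PI [38:4], PI [38:5], PS [40:4]) in
  alveolar tissue, β = 1.2 log2 per latent SD — deliberately confounded, as
  ageing and emphysema are in real cohorts. Inflammation couples DAG/TAG up
  and long-chain SM/PG down.

What it does **not** emulate: mass spectra, isotope interference,
instrument drift, abundance-dependent missingness, non-lognormal tails, or
any real covariance between lipid classes beyond what closure induces. A
green test on synthetic data therefore establishes that the statistics do
what they claim on data with this structure — not that the biology of any
particular cohort will behave.

### Power properties and cohort size

The module property "cross-validation flags the coupled responses in ≥90% of
replicates" is evaluated on 40-patient control-only cohorts. At the
26-patient preset (20 alveolar samples) the flag rate plateaus near 85%
regardless of coupling strength: the limit is CV variance with two-sample
validation folds, plus the increasing log-linear mismatch when couplings get
large (mol% is exponential in the latent, the response is linear). Power
properties are statements about the method, so they are tested at a sample
size where the method's assumptions can hold; the preset keeps its
real-cohort geometry, and its own end-to-end criterion (panel AUC ≥ 0.9,
negative mean tumour score) is tested at 26 patients. For the same reason
the cross-validation power criterion plants a one-latent-factor signal
(X = t·bᵀ + E, Y = t + ε at SNR 3): that is the covariance structure PLS
assumes, and the structure the generator itself plants; a diffuse
100-coefficient signal without latent X structure is not reachable by any
PLS at n = 40 and is not claimed.

## Known limitations

- Isobaric-overlap revision of identifications is not implemented (no
  algorithm is specifiable from the available description).
- The t-test treats tumour and alveolar samples as unpaired even for matched
  pairs; with positive within-patient correlation this is conservative.
- Q² pooling across responses is secondary (`Q2_total`); per-response Q² is
  the primary criterion.
- The free-cholesterol assay is external; `FC` is just a column.
- No classifier beyond the fixed-form score, and no nonlinear/kernel PLS.
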