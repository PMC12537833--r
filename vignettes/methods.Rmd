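---
title: "Methods: craving prediction from cue-reactivity beta maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: craving prediction from cue-reactivity beta maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cravingsig)
```

## The model

`cravingsig` predicts a block-level ordinal craving rating $y \in
\{1,2,3,4\}$ from a voxelwise beta-coefficient map $x \in
\mathbb{R}^p$ estimated for that cue block. The fitted predictor is a
composition of four stages, each fit on training subjects only:

1. **Variance filter.** Columns with unbiased sample variance below
   0.001 are removed. With sparse beta maps this deletes, at minimum,
   every out-of-mask voxel (exact zeros) and any constant column, and
   it guarantees a strictly positive scale for the next stage.
2. **Standardization.** Each kept column is z-scored with training
   mean $\mu_j$ and SD $\sigma_j$.
3. **Reduction.** Either projection onto the leading $k$ principal
   components of the standardized training matrix (eigenvector matrix
   $V$, orthonormal columns, descending explained variance), or
   selection of the $k$ columns with the largest one-way ANOVA $F$
   statistic grouping betas by rating level.
4. **Regression.** One of: ordinary least squares, ridge, lasso,
   elastic net, random forest, gradient-boosted trees. The default and
   empirically selected configuration is PCA + OLS, which admits exact
   back-projection.

For a linear fit on PCA scores, the reduced-space coefficients $B$
collapse with $V$ into a single voxel-space weight vector — the **VB
signature**. Two variants are kept deliberately: `vb` $= VB$ lives in
the standardized voxel space and is what display and regional summaries
use; `vb_raw` $= VB / \sigma$ additionally folds in the scaler so that
with the adjusted intercept $b_0' = b_0 - \sum_j \mu_j (VB)_j /
\sigma_j$ the identity $\hat y = \langle x_{\mathrm{raw}},
\mathrm{vb\_raw} \rangle + b_0'$ reproduces the pipeline's predictions
to machine precision (this identity is asserted in the test suite at
$10^{-8}$). Conflating the two variants would silently rescale the map
by each voxel's SD, so both are carried and labeled.

### Assumptions

* Samples are per-block beta maps, eight per subject, with the rating
  collected immediately after each block; within-subject rating
  variation is the signal of interest.
* Inputs are co-registered to a common grid; no spatial normalization,
  smoothing, or GLM fitting happens here — the pipeline starts at
  betas.
* Generalization is across subjects, so all splitting is by subject:
  no subject's samples may appear on both sides of any train/test
  boundary. This is enforced by an assertion that aborts the run,
  tested by planting a duplicate subject ID.
* No mixed-effects structure is modeled: the estimator is a fixed
  pattern shared across subjects, evaluated on unseen subjects.

## Evaluation and inference

**Splits.** `make_split()` holds out $\lceil 0.2\,n \rceil$ subjects
(for 51 analyzed subjects: 11 held out, 40 fitting — the ceiling is
what uniquely reproduces that arithmetic) and deals the rest into $k=5$
folds differing in size by at most one.

**Stratified metrics.** RMSE and MAE are computed within each observed
rating level and averaged with equal weight, neutralizing rating
imbalance. Pearson $r$ is pooled across levels: within a single level
the true ratings are constant and a per-level correlation is undefined,
so a "stratified $r$" has no meaning — this is a deliberate
interpretation recorded here.

**Repeated CV.** Reported means and SDs are distributions over repeated
5-fold deals with fresh child seeds (default 50 repetitions in the
pipeline entry point; the repetition count is a package choice — the
source analysis does not fix one).

**Permutation null.** Target labels are shuffled across all fitting
samples (features untouched; a within-subject shuffle is available as a
flag) and the full CV evaluation re-runs per permutation. Because the
variance filter, scaler and PCA do not depend on the target, the
fold-wise projections are computed once and only the regressor is refit
per permutation — an exact optimization that makes 1000 permutations
routine. For the high/low task the binary labels and raw extreme
ratings are permuted jointly across the extreme-block samples; the
extreme-block subset itself is held fixed, since it is part of the task
definition rather than of the hypothesis under test.

**p, power, effects.** $p = (1 + \#\{\text{null at least as good as
the observed mean}\}) / (1 + n_{\mathrm{perm}})$ — the add-one rule
keeps $p > 0$. Power is the fraction of the observed distribution
beyond the null's 5 % critical value, so power $\approx \alpha$ when
observed and null coincide (a self-calibration property the tests
check). Effect sizes pass a Shapiro–Wilk gate at $\alpha = 0.05$ on the
observed distribution: normal-looking distributions get Cohen's $d$
with a Student-t CI of the mean; otherwise Cliff's $\Delta$ with a
percentile-bootstrap CI (1000 resamples). Effects are oriented so that
better-than-null performance is positive regardless of the metric's
direction.

## The two classifiers

Both classifiers reuse the regression pipeline unchanged and differ
only in target, component count and threshold mapping:

* **High/low craving** (PCA = 50, chosen for the smaller sample).
  Per subject, only the first-occurring minimum-rating block (label 0)
  and first-occurring maximum-rating block (label 1) are kept; subjects
  with constant ratings are dropped, so classes are exactly balanced.
  The regressor is trained on the raw 1–4 ratings of those blocks; a
  decision threshold maximizing F1 is re-optimized on each CV
  iteration's *training* predictions and applied to its test
  predictions (optimizing on test would leak). RMSE for this task is
  scored against the raw extreme ratings, not the 0/1 labels — the
  magnitude of that error only makes sense on the rating scale.
* **Cue type** (PCA = 100). The regressor is trained on the 0/1 cue
  code and thresholded at 0.5, with a prediction exactly at the
  boundary mapping to the drug class (a fixed convention for
  determinism).

A known structural effect, visible on synthetic cohorts: when the
training fit is strong, training predictions span nearly the full
rating range while test predictions shrink toward the grand mean, so
the train-derived F1 threshold can sit below most test predictions.
Accuracy then lags the AUC (which is threshold-free). This is a
faithful consequence of optimizing the threshold on training
predictions; it attenuates as the signal weakens toward realistic
levels.

## The synthetic generator

No clinical dataset ships with the package, so `generate_cohort()`
emulates the statistical frame the analysis assumes:

* **Cohort frame:** 69 recruited subjects, 18 flagged for exclusion
  (ID filter applied before any splitting), 51 analyzed; 8 blocks per
  subject alternating drug/neutral starting from neutral; 6 images ×
  5 s + 0.2 s gaps = 31 s blocks; TR 2 s, 196 volumes.
* **Beta maps:** a 16×16×16 grid (4096 voxels) with a centered
  quasi-spherical mask covering 60 % of voxels; out-of-mask voxels are
  exactly zero, emulating the large zero fraction of masked clinical
  maps at desk scale (the ~10⁶-voxel scale of real data is
  configurable upward but not the default).
* **Planted signal:** block $b$ of subject $i$ has intensity
  $a_{ib} = \mathrm{amp}(\mathrm{cue}) \cdot u_{ib}$,
  $u_{ib} \sim U(0.25, 1.75)$, with amplitudes 2.2 (drug) vs 1.0
  (neutral); betas are
  $\mathrm{mask} \circ (a_{ib} w + o_i f + \varepsilon)$ with
  $w$ the unit-norm signature, $f$ a fixed subject-offset field,
  $o_i \sim N(0, 0.35)$, $\varepsilon \sim N(0, 0.35)$ per voxel. The
  latent craving score $a_{ib} + o_i + \eta_{ib}$ (same $a_{ib}$) is
  cut at thresholds (0.9, 1.6, 2.3) into ratings 1–4. These defaults
  were chosen once to produce all four rating levels, drug > neutral
  mean ratings, and a rating SD near one rating point; fixed
  thresholds (rather than rank quantiles) keep the noiseless limit
  deterministic.
* **Signature shape:** $w$ is a constant-magnitude sign pattern
  (±1 on 150 support voxels, normalized). The pipeline standardizes
  every voxel, which equalizes signal scale across voxels; a
  varied-magnitude $w$ would therefore be unrecoverable in the cosine
  sense by construction (the standardized read-out approximates
  $\mathrm{sign}(w)/|w|$), whereas a sign pattern is exactly the kind
  of structure the standardized linear model can recover.
* **Reproducibility:** all draws descend from one master seed through
  per-subject child seeds, so any subject subset is bit-reproducible.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: spatial autocorrelation and smoothness of
BOLD maps, hemodynamic and GLM estimation artifacts, scanner/site
effects, non-linear brain–behavior relationships, heavy-tailed rating
behavior, and realistic (much lower) signal-to-noise. Synthetic
performance numbers are upper bounds on method behavior, not forecasts
for clinical data.

### A non-obvious numerical point: recovery vs noise

Parameter-recovery tests use a "high-SNR" cohort at `noise_sd =
subject_sd = 0.1`. Recovery of $w$ is *non-monotone* in the noise
level: the rating is a quantized staircase of the latent score, and the
quantization residual gets fit by the weakest retained principal
components. As voxel noise shrinks, those components' eigenvalues
collapse and their fitted coefficients explode ($B_k \propto
1/\lambda_k$), drowning the signature; as noise grows, ordinary
estimation error dominates. Recovery peaks in between, which is why the
recovery cohort is defined at 0.1 rather than at zero noise.

## Numerical choices

* PCA is computed from the eigendecomposition of the sample Gram matrix
  when $n < p$ (algebraically the economy SVD); component signs are
  fixed by forcing each component's largest-magnitude loading positive,
  making repeated fits — and therefore signature maps — bit-identical.
* Component counts are capped at $\min(n-1, p_{\mathrm{kept}})$ and
  further truncated at the numerical rank; a degenerate (rank-1)
  noiseless cohort fits with a single component rather than failing.
* Penalized linear fits solve the elastic-net objective at the
  requested penalty exactly (convergence threshold $10^{-10}$);
  a constant target short-circuits every family to the constant
  predictor.
* Grid-search ties break deterministically: fewer components first,
  then the simpler family in menu order. Invalid candidates (e.g. more
  components than training samples) are reported failed with their
  reason, never dropped silently.
* The midrank AUC equals the normalized Mann–Whitney statistic
  (tie-aware); AUC-PR uses step integration over unique thresholds.
  All-equal scores give AUC 0.5.
* F1-threshold candidates are the midpoints between consecutive sorted
  unique predictions plus one candidate below the minimum and one
  above the maximum; ties resolve to the lowest threshold.
* Cohort beta volumes are written at float64 so write→read round trips
  are bit-exact; signature and mask volumes are float32 (display
  artifacts). In-memory computation is float64 throughout. Voxel order
  is fixed as column-major (x-fastest) flattening.
* Empty atlas regions are reported as missing (`NA`), never as zero —
  a zero would be indistinguishable from a genuine null contribution.

## Problem sizes used by the tests

Unit tests run on 8³-grid cohorts of 12 subjects. The acceptance suite
uses the full default frame (4096 voxels, 51 analyzed subjects) with
50-repetition CV distributions and 200-permutation nulls, and a
100-repetition calibration study of the permutation p-value (labels
shuffled independently of features; the rejection rate at
$\alpha = 0.05$ must fall in 5 % ± 4). These sizes are the package's
own testing choices; the full 1000-permutation setting remains the
config default for analyses via `inference: n_perm`.

## Known limitations

* ANOVA-based selection has no eigenvector matrix, so no VB
  back-projection exists on that branch (the exported function refuses
  it rather than approximating).
* The grid search runs once on the fitting set with subject-level
  internal CV; it is not re-nested inside each outer fold.
* Whether ANOVA selection should group by rating, by cue, or treat the
  rating as continuous is genuinely open; grouping by rating level is
  the package's documented choice.
* Bootstrap CIs are percentile intervals of the mean; no BCa
  correction.
* The permutation p-value compares the *mean* of the observed
  distribution against the null sample — one consistent reading of
  "counting from the critical value"; comparing full distributions
  would require a different test statistic.
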