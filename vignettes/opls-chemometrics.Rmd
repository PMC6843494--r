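---
title: "Methods: OPLS-DA chemometrics for two-arm metabolomics studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OPLS-DA chemometrics for two-arm metabolomics studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oplsmet)
```

This vignette documents the statistical model the package implements, the
choices made where the conventional workflow leaves details open, and
what the simulation-based tests do and do not establish.

## The analysis problem

A two-arm dietary-supplementation trial delivers plasma samples at fixed
time points; GC-TOF-MS yields a peak-area table of ~95 identified
metabolites per analytical batch, with 9–31 subjects per arm. The
questions are (i) whether the treated arm's metabolome differs from
placebo at a given time point, (ii) which metabolites carry the
difference and in which direction, and (iii) whether those directions
replicate across batches and validation cohorts. Because metabolite
levels are strongly correlated (few pathways act independently),
latent-variable models complement per-metabolite tests.

## Internal-standard normalisation

Eleven internal standards, spiked at a fixed amount into every sample,
track injection and extraction efficiency. Each standard is scaled to
unit variance **without mean-centring** and a one-component NIPALS PCA is
fitted; the first score $t_1$ of each sample is its overall intensity
factor, and all peak areas of the sample are divided by it.

Centring is deliberately omitted: a centred first component contrasts
samples around the mean and its scores can be zero or negative, making
division undefined. Uncentred, with all standard areas positive, $t_1$
is a weighted mean intensity and stays positive for any consistent
standards panel; a non-positive score is treated as an error because it
signals standards that do not share a common intensity factor. The
component sign is fixed so the mean score is positive. A constant
(zero-variance) standard is scaled by its mean instead of its SD, so it
contributes a constant column rather than a division by zero.

Two caveats are documented rather than hidden. First, because the
scaling and weights are estimated from all samples, multiplying one
sample's areas and standards by a common factor reproduces its
normalised profile only approximately; the discrepancy vanishes with
cohort size and with the size of the factor (the suite verifies 0.5%
agreement at $n = 200$ and a 1.2-fold rescaling). Second, normalisation
removes per-sample dilution but not metabolite-specific drift.

## Scaling conventions

Unit-variance scaling uses the **population** (1/n) standard deviation
throughout — one convention, applied everywhere, so that scores,
loadings and p(corr) are mutually consistent. Missing cells are excluded
from the mean/SD computation and imputed at the column mean (0 after
scaling), which is neutral for PCA and PLS fits. Zero-variance columns
are an error naming the offending variable.

## NIPALS PCA

Components are extracted sequentially by the NIPALS recursion with a
deterministic start (the column with the largest remaining sum of
squares), convergence tolerance $10^{-10}$ on the relative change of the
score vector, and at most 500 iterations (non-convergence is an error
naming the component). Loadings are unit-norm; the sign of each loading
vector is fixed so its largest-magnitude entry is positive, making
score plots reproducible. New samples are projected with the stored
centring/scaling; projecting the training data reproduces the training
scores because the loadings are orthonormal.

Hotelling's $T^2$ uses the training score variances, with the control
limit $A(n-1)/(n-A) \, F_{1-\alpha}(A, n-A)$ for $A$ components and $n$
training samples — the ellipse drawn on conventional score plots.

Representative-subject selection ("multivariate design") works on the
first two score dimensions: per quadrant, first the sample farthest from
the origin, then samples maximising the minimum distance to those
already chosen; centre picks are the samples nearest the origin. The
field's practice does not specify how the per-quadrant "extremes" are
chosen, so max-spread was adopted for determinism; boundary scores
(exactly 0) count to the positive side, and all ties break by sample-id
order.

## OPLS-DA

With UV-scaled $X$ and centred class vector $y$ (placebo = 0,
active = 1), each orthogonal round computes

$$w \propto X' y,\quad t = X w,\quad p = X' t / t' t,\quad
  w_\perp \propto p - (w' p) w,\quad t_\perp = X w_\perp,$$

deflates $X$ by $t_\perp p_\perp'$, and after `n_orthogonal` rounds fits
the single predictive component on the filtered matrix. With zero
orthogonal components the model coincides with one-component PLS1, and
with one orthogonal component its training predictions equal those of
two-component PLS — both identities are verified against independent
reference implementations in the tests. The default `n_orthogonal = 1`
matches the one-predictive-plus-one-orthogonal structure conventional for
two-class metabolomics models at these sample sizes.

Diagnostics: R²X is the fraction of scaled-X sum of squares captured by
predictive plus orthogonal components; R²Y(cum) the fraction of class
variance explained; p(corr) the Pearson correlation of each scaled
variable with the predictive score, bounded in $[-1, 1]$ and comparable
across models; VIP aggregates each variable's squared weights over all
components, weighted by explained y-variance (predictive) and explained
X-variance (orthogonal) — the "total VIP" convention of the major
commercial package — and normalised so $\sum \mathrm{VIP}^2 = K$. The
conventional selection threshold 0.8 applies to this total VIP.

## Cross-validation and the predicted-y test

Folds are assigned deterministically: samples sorted by (class, id) and
dealt round-robin, so both classes appear in every fold and reruns are
bit-identical. The commercial software's exact fold policy is not
knowable from outside; determinism was preferred over guessing. Each
fold is predicted by a model refitted without it;
$Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}(y)$. Group separation is tested by
a Welch two-sample, two-tailed t-test on the out-of-fold predicted
values (the pooled-variance variant is a plausible alternative; Welch is
consistent with the package's univariate convention and invariant to
affine transforms of the predictions).

## Jack-knife confidence intervals

For each of the $G$ cross-validation rounds the model is refitted
without that fold and the per-variable statistic recorded — p(corr) by
default; effective regression coefficients as an option. Which statistic
the original software jack-knifes for its significance calls is not
documented; p(corr) was chosen because the significance calls accompany
the p(corr) loading display, and both options are exposed. Each
sub-model's statistic vector is sign-aligned to the full model's
predictive score (the latent direction is defined only up to sign)
before computing

$$\mathrm{SE} = \sqrt{\tfrac{G-1}{G} \sum_g (s_g - \bar s)^2},\qquad
  \mathrm{CI} = \hat s \pm t_{1-\alpha/2,\,G-1} \cdot \mathrm{SE},$$

with the CI centred on the full-model statistic. A variable is flagged
when its CI excludes zero; direction calls combine this with the
VIP ≥ 0.8 screen (UP / DOWN / NONE).

**Calibration.** Under a global null at $n = 9 + 9$ with 95 metabolites
the average jack-knife SE matches the true sampling SD of p(corr)
almost exactly, yet the flag rate sits somewhat above the nominal 5%
(the suite measures it on the order of 9–12%): with only seven folds the
SE estimate is variable, and replicates where it is small flag too
readily. This mild anti-conservativeness is a property of jack-knifing
resampled latent directions at small $G$, not an implementation defect;
the acceptance test therefore asserts the rate stays on the order of
the nominal level (within a factor ~2.5) rather than exactly at it.
Users should read the flags as a screen, to be confirmed univariately —
which is how the workflow uses them.

## Univariate statistics

Per-metabolite comparisons are Welch (unequal-variance, two-tailed)
t-tests on non-missing values, reported as raw p-values (the workflow's
convention), with an optional Benjamini–Hochberg column. Metabolites
with fewer than two observations in either arm are flagged untestable
and excluded with a message.

Baseline contingency tables use Pearson chi-square with one degree of
freedom and **no continuity correction**: this convention reproduces 11
of the 12 testable printed baseline p-values of the packaged `table1`
fixture at two decimals. The exception, the Hypertension row, prints
0.91 where the counts give 0.37 under any standard 2×2 test — most
plausibly a typo in the source table; it is documented and excluded from
the fixture assertions. Rows with a zero observed cell are reported as
`NA` (the chi-square approximation is meaningless there at these group
sizes), mirroring the printed "n/a".

## Multi-study synthesis

Per-batch p(corr) vectors are stacked into a batches × metabolites
matrix and a one-component PCA **with no scaling and no centring** is
fitted; the first loading $p_1$ (unit norm) is the combined metabolic
profile. Metabolites absent from a batch are mean-imputed across the
remaining batches — preserving the shared-direction signal without
inventing magnitude — and the sign of $p_1$ is anchored to positive
correlation with the first batch.

Concordance between a reference study and validation studies counts a
metabolite as evaluated when its reference call is not MISSING, and as
congruent when its symbol (UP, DOWN, **or NONE**) equals the symbol in
at least one comparison study; NONE = NONE counts as agreement because
the question is "congruence in change, or no change". Under this rule
the packaged three-study direction table yields 62 of 107 (57.9%); the
stricter changed-only reading would give 55 and is available through
`pairwise_agreement(..., changed_only = TRUE)`, which likewise exposes
both denominators for between-study agreement (the summary phrasing
"detected in at least two studies" is ambiguous, so both modes are
provided rather than guessing one).

## The synthetic cohort generator

Ground-truth cohorts are drawn on the log scale,

$$\log a_{sm} = \mu_m + \text{block}_{sm} + \delta_m \cdot 1[\text{active}]
  + \beta_{b(s)} + d_s + \varepsilon_{sm},$$

so areas are strictly positive and dilution/batch effects are
multiplicative, as is standard for GC-MS peak areas. Defaults emulate a
main-study batch: 95 metabolites, 11 internal standards, 19 metabolites
(20%) lowered to 0.8-fold in the active arm as a correlated
"amino-acid-like" block, 7 (8%) raised to 1.25-fold as a
"saturated-fatty-acid-like" block, within-block correlation 0.5 via a
shared latent factor, per-sample dilution log-SD 0.3, per-batch offset
log-SD 0.1, and affected counts fixed as `floor(fraction × K)` for
determinism. Internal standards carry the dilution and batch terms but
no group effect and a small analytical log-SD (0.05).

The residual log-SD default of 0.18 is the one free noise parameter. It
was set so that a 0.8-fold group difference attains a two-sample t-test
p of about 0.02 at nine subjects per arm (standardised effect
$|\log 0.8| / 0.18 \approx 1.24$) — the operating point reported for
the significant metabolites of such studies. The non-compliant-control
helper (`plant_outlier`) applies the active-arm multiplicative effect to
one placebo sample, which equals re-drawing it under the active model
with the same noise realisation and makes the operation exactly
invertible.

What the generator does **not** emulate: retention-time drift and
peak-shape artefacts, metabolite-specific (non-common) dilution
response, heavy-tailed or skewed residuals beyond log-normality,
missingness that depends on abundance (censoring at the detection
limit), and correlation structure richer than two blocks. Passing
simulation tests therefore establish internal correctness and
calibration under a plausible generative model — not performance on any
particular real cohort.

## Problem sizes and determinism

The test suite and the acceptance script run at the study's natural
scale: cohorts of 9 + 9 subjects with 95 metabolites; 200 null
replicates for jack-knife calibration; 400 label permutations for the
permuted-Q² check; 50 seeds for power; 20 seeds for direction recovery
and normalisation CV reduction. A full run of the suite completes in
well under a minute. Every stochastic step derives from an explicit
seed, and the pipeline itself uses no randomness: identical inputs and
configuration give bit-identical outputs, which the suite asserts.

## Known limitations

* The jack-knife flag rate under the null is mildly anti-conservative
  (see above); treat flags as a screen.
* Model statistics from the original plasma cohorts (R²X, R²Y, Q², the
  predicted-y p-value) depend on data that are not publicly deposited
  and cannot be reproduced; the packaged fixtures cover only the
  printed summary tables.
* Only two-class OPLS-DA is implemented (no multi-class, no O2PLS), and
  missing values are mean-imputed rather than modelled.
* `combine_pcorr` assumes batches share most metabolites; with few
  shared metabolites the mean-imputation dominates and the combined
  profile degrades.
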