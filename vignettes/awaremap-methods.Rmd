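---
title: "Methods: memory awareness and voxelwise neurodegeneration mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: memory awareness and voxelwise neurodegeneration mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Subjective memory decline (SMD) — a person's self-report of worsening memory
— changes meaning along the Alzheimer's clinical continuum. In cognitively
unimpaired people and patients with subjective cognitive decline (SCD),
stronger complaints can track early neurodegeneration; in mild cognitive
impairment (MCI) and dementia, awareness of deficits erodes (anosognosia), so
*weaker* complaints can accompany *more* neurodegeneration. `awaremap`
implements the full analysis used to characterize this switch:

1. **Normative w-scores.** Raw subjective and objective memory scores are
   converted to age-, sex- and education-adjusted z-scores relative to the
   control group.
2. **Delta memory-awareness index.** The SMD w-score is reversed so higher
   means better self-rated memory, and
   `delta = objmem_w - smd_w_reversed`. Negative delta means the participant
   underestimates their difficulties (the anosognosia direction).
3. **Group comparisons.** One-way ANOVA with Tukey-Kramer post hoc tests for
   continuous scores; Pearson chi-square for the percentage of
   positive/negative delta per group.
4. **Voxelwise GLMs.** Mass-univariate regression of neurodegeneration maps
   (grey-matter volume or FDG metabolism) on the SMD w-score, per clinical
   group, and across the whole sample with a continuous SMD-by-MMSE (or
   SMD-by-episodic-memory) interaction. Age, sex and education are regressed
   out of every model.
5. **Cluster-extent inference.** Voxelwise one-sided p < 0.005 combined with
   a minimum cluster size `k_min` derived by Monte-Carlo simulation of
   smooth Gaussian null fields so that the family-wise probability of a
   surviving cluster is below 0.05. Suprathreshold clusters smaller than
   `k_min` are reported as trends.
6. **Extraction and stratified correlations.** Mean values in surviving
   clusters are extracted per participant and correlated with the SMD
   w-score within MMSE tertiles, which is where the sign switch becomes
   visible.

The restricted clinical cohorts behind the original findings are not
required: a seeded synthetic-data generator reproduces the statistical
structure the analysis assumes, so every stage is exercised end to end by
the tests and by the scripts under `analysis/`.

## Normative model and w-scores

For outcome $y$ (raw SMD or objective memory score) the normative model is
ordinary least squares on the controls only:

$$y = \beta_0 + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{sex} +
\beta_3\,\mathrm{education} + \varepsilon,$$

with sex coded female = 0 / male = 1 (any consistent coding gives identical
w-scores; this is asserted by a test). For every participant,
$w = (y - \hat y)/\hat\sigma$, where $\hat\sigma$ uses denominator $n-4$
(the unbiased regression sigma; the choice of denominator is a package
decision, documented because conventions differ). At least 5 controls with
complete data are required; fully collinear covariates (e.g. all controls
identical) degrade gracefully to an intercept-only fit via aliasing.

**Reversal as negation.** The SMD scale is reversed so that higher = better
self-rated memory. Because the normative model is linear, reversing the raw
scale as `max - raw` and re-fitting is exactly equivalent to negating the
w-score of the raw scale; the package uses the negation, which needs no
questionnaire maximum. The equivalence is asserted numerically to 1e-10.

**Delta ties.** `delta == 0` is classified as positive (non-negative) — a
measure-zero event under continuous scores; the dichotomy otherwise follows
the sign.

## Synthetic-data generator

`generate_cohort()` draws, per clinical group, Gaussian age, education and
MMSE (MMSE clipped to [0, 30], education to non-negative), Bernoulli sex,
and a bivariate-normal pair of raw subjective/objective scores with a
configurable within-group correlation (default 0, since no within-group
value is reported to emulate) and an optional additive sex effect (default
0, so covariate adjustment can be tested with and without genuine sex
signal).

The shipped defaults are the study conditions: group sizes 67/36/60/37 and
the published demographic means and SDs (e.g. control MMSE 28.95 ± 1.04).
The subjective/objective raw-score distributions are not published as
tables, so the defaults were calibrated analytically — before any
acceptance run — to reproduce the published per-group percentages of
negative delta scores (46.27/19.44/73.33/89.66%): under normal theory the
percent negative is $\Phi(-\mu_\delta/\sigma_\delta)$, giving objective
means 12/11.5/6/2 (SD 2.5/2.5/3/3) and subjective means 8/13/14/15 (SD
4/4/5/5) on the raw scales. Complaints are therefore elevated in every
patient group and rise mildly along the continuum while objective memory
declines — the qualitative group pattern of the source cohorts.

Note one numerical consequence of clipping: the clipped control MMSE mean
converges to the clipped-normal mean (≈ 28.86), about 0.09 below the
nominal 28.95; the convergence test asserts agreement with the analytic
clipped mean.

`generate_volumes()` plants, inside a chosen region,

$$v = \mathrm{baseline} + \mathrm{slope}(\mathrm{stratum})\cdot w_{\mathrm{SMD}}
 + \gamma\, w_{\mathrm{SMD}}(\mathrm{MMSE}-\overline{\mathrm{MMSE}}),$$

and adds spatially smoothed Gaussian noise everywhere in the mask. Slopes
are planted on the *w-score* scale so fitted coefficients are directly
comparable to planted ones, and MMSE is centred at the sample mean so the
main effect and interaction are orthogonal and separately recoverable.
Strata may be clinical groups or MMSE tertiles (computed with the same
tertile rule the analysis uses, keeping generation and analysis
consistent).

**Noise model.** White Gaussian noise is convolved with a separable
Gaussian kernel by *circular* (periodic) convolution and scaled by the
kernel L2 norm, which makes the marginal voxel SD exactly `noise_sd` at
every voxel and the field exactly stationary, for any smoothness setting.
This keeps the planted effect size interpretable across FWHM choices.

What the generator does **not** emulate: anatomy and tissue contrast,
atlas-shaped regions, PET physics and partial-volume effects,
inhomogeneous smoothness, registration error, and site effects. Passing
tests therefore demonstrate the *statistical* correctness of the pipeline
under its own assumptions, not robustness to the messiness of real imaging
data.

## Voxelwise GLM engine

`fit_voxelwise()` computes one QR factorization of the design and applies
it to all in-mask voxels at once; the contract (asserted against
brute-force per-voxel regressions to 1e-8) is that results are identical to
independent voxelwise OLS and independent of voxel order. The t-map is
`beta/SE` for one named target column with `df = n - rank(X)`. Rank
deficiency is an error naming the collinear columns (a constant moderator,
for instance, makes the product term collinear with the SMD column).
Standardized residuals (per-voxel residual divided by the voxel's residual
SD) are retained for smoothness estimation.

Per-group associations are obtained by fitting within each clinical group
separately, matching how the per-group regressions are reported; the
interaction model
`1 + smd_w + moderator + smd_w:moderator + age + sex + education` is fitted
on the whole sample with the moderator mean-centred before the product is
formed (centring reduces collinearity and makes the SMD main effect
interpretable at average MMSE). The same code path accepts the
episodic-memory w-score as the moderator.

## Cluster-extent inference

**Smoothness.** `estimate_fwhm()` uses the first-difference
Gaussian-autocorrelation relation per axis,
$\mathrm{FWHM} = \sqrt{-2\ln 2 / \ln \rho}$ with
$\rho = 1 - \mathrm{var}(\Delta)/2$ estimated from standardized residual
volumes pooled over in-mask neighbour pairs. White noise gives FWHM near 0;
a known σ = 2 kernel is recovered within 10% (asserted). Ratios outside
(0, 1) are clipped with a warning (from above at a FWHM equal to the axis
extent).

**Null simulation.** `simulate_cluster_threshold()` draws white noise on
the mask bounding box, smooths it to the estimated FWHM (geometric mean of
the per-axis estimates applied isotropically by default; an anisotropic
mode exists), thresholds one-sided at $z_{1-p}$ and records the maximum
connected-component size per iteration; `k_min` is the smallest extent
whose exceedance fraction is at most the corrected alpha. Because the
periodic-kernel construction yields exactly unit marginal variance, no
empirical rescaling is applied — an empirical in-mask standardization
would couple voxels and distort the null on small masks. When no extent
controls the error the result is explicitly flagged saturated rather than
silently usable: `k_min` is mask size + 1 (or the mask size itself in the
fully degenerate `voxel_p >= 1` case, where every voxel is always
suprathreshold).

Null fields are Gaussian even though the real maps are t-maps — standard
Monte-Carlo practice, and a documented approximation: with the residual
degrees of freedom used here (≥ 50) the t tail behaves closely enough that
the measured family-wise error stays within two binomial standard errors
of nominal (asserted on 200 null datasets).

**Thresholding.** `threshold_and_cluster()` converts the t-map to one-sided
voxel p-values at the map's residual df, labels suprathreshold voxels by
connected components (default connectivity 18, face+edge, the common SPM
practice; 6 and 26 selectable), and classifies clusters as significant
(size ≥ `k_min`) or trend. Negative and positive directions are analyzed
separately, mirroring the separate reporting of negative and positive
interactions; a two-sided analysis can be had by halving `voxel_p`.

## Tertiles and stratified correlations

`tertile_split()` uses rank-based thirds with tied values assigned entirely
to the lower stratum; a fixed-cutpoint mode (high > 28, low < 27) matches
the published MMSE cutoffs. `stratified_correlations()` reports Pearson r
with two-sided p per stratum, excludes strata with fewer than 3
participants with a warning, and flags (rather than fails on) constant
input.

## Problem sizes and numerical choices

The tests and the acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical properties are identifiable:

- family-wise error: 200 null datasets, n = 60, 24×24×24 mask, FWHM 3
  voxels, `k_min` from a 1,000-iteration simulation at the family's median
  residual smoothness (the 200 datasets share one generation setting, i.e.
  one smoothness family);
- sign-switch recovery: 10 seeds, 60 participants per stratum, planted
  slopes ∓0.8 at noise SD 1, 6×6×6-voxel planted cube in a 24³ mask,
  success = significant negative-interaction cluster with Dice ≥ 0.3 plus
  opposite-sign tertile correlations;
- engine equivalence: 100 random 4×4×4 stacks at n = 12 against per-voxel
  `lm()`;
- production cluster simulations should use `n_iter = 10000`; tests use
  1,000 for percentile stability at reasonable runtime.

Seeds are explicit everywhere; identical seeds give bit-identical cohorts,
volumes and manifests (figures embed timestamps and are listed unhashed).

## Known limitations

- Gaussian (not t) null fields; isotropic smoothness by default.
- Periodic noise wrapping is exact for stationarity but means opposite
  faces of the simulated box are correlated at large FWHM relative to the
  box size.
- The normative model is linear; quantile or GAM normative models are out
  of scope.
- Behavioural group comparisons are w-score-adjusted, not ANCOVA-adjusted;
  no mixed models or longitudinal analyses.
- Amyloid status is consumed as a given flag; no SUVr quantification.
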