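# awaremap

Analysis pipeline for **subjective memory decline (SMD) across the
Alzheimer's clinical continuum**: how self-reported memory problems relate
to objective performance and to voxelwise neurodegeneration (grey-matter
volume, FDG metabolism) in controls, subjective cognitive decline (SCD),
mild cognitive impairment (MCI) and dementia.

The package is written for neuropsychology/neuroimaging researchers who
want the full statistical chain of such a study as tested, reusable code:

1. **Normative w-scores** — raw scores become age-, sex- and
   education-adjusted z-scores relative to controls:
   `w = (y - ŷ(age, sex, edu)) / σ̂`, with the normative regression fitted
   on controls only.
2. **Delta memory-awareness index** — the SMD w-score is reversed (higher =
   better self-rated memory) and `delta = w_objective - w_SMD,reversed`.
   Negative delta = underestimating one's difficulties (the anosognosia
   direction); positive = overestimating them.
3. **Group comparisons** — one-way ANOVA + Tukey-Kramer post hoc tests;
   Pearson χ² on the percentage of negative vs positive delta per group.
4. **Voxelwise GLMs** — mass-univariate OLS of neurodegeneration maps on
   the SMD w-score, per clinical group and with a continuous
   `SMD × MMSE` interaction, always adjusting for age, sex and education;
   signed t-maps with the interaction's negative and positive directions
   analyzed separately.
5. **Cluster-extent inference** — voxelwise one-sided p < 0.005 combined
   with a minimum cluster size `k_min` derived by Monte-Carlo simulation of
   smooth Gaussian null fields (smoothness estimated from the model
   residuals) for family-wise corrected p < 0.05; smaller suprathreshold
   clusters are reported as trends.
6. **Extraction** — per-participant cluster means and MMSE-tertile-
   stratified correlations, where the stage-dependent sign switch of the
   SMD-neurodegeneration association becomes visible.

A seeded synthetic-data generator (`cohort_spec()`, `generate_cohort()`,
`effect_spec()`, `generate_volumes()`) reproduces the statistical structure
the analysis assumes — published group score distributions and planted
voxelwise effects whose sign flips with disease stage — so the entire
pipeline runs and is tested without access to any restricted cohort.

## Worked example

`analysis/` contains the numbered drivers of the full study
(`01_simulate_cohort.R` … `05_error_control.R`). The core of
`03_voxelwise_pipeline.R`:

```r
library(awaremap)

mask <- array(TRUE, c(24, 24, 24))
region <- array(FALSE, c(24, 24, 24))
region[10:15, 10:15, 10:15] <- TRUE          # planted sign-switch cluster

cfg <- run_config(
  cohort = cohort_spec(seed = 1),            # groups 67/36/60/37, published
                                             # demographic distributions
  effect = effect_spec(region,
                       slope_by_stratum = c(high = -0.8, low = 0.8),
                       noise_sd = 1, smoothing_fwhm_vox = 3, seed = 1),
  mask = mask, moderator = "mmse",
  voxel_p = 0.005, alpha = 0.05, n_iter = 1000, seed = 2026)

manifest <- run_pipeline(cfg, "results/pipeline")
```

Output (abridged) from this exact run:

```
  participants: 200
  per-group maps: control, scd, mci, dementia
  residual FWHM (vox): 2.99 x 2.97 x 2.98
  k_min: 45 voxels
  significant clusters per map/direction:
    ... interaction_negative 1 ...

Extracted-cluster correlations with the SMD w-score by MMSE tertile:
  stratum  n       r        p
      low 67  0.9249 5.29e-29
      mid 67 -0.0505 6.85e-01
     high 66 -0.9082 6.78e-26
```

Reading this: the residual smoothness (≈ 3 voxels FWHM) drives a
Monte-Carlo minimum cluster size of 45 voxels; the SMD × MMSE interaction
map contains one significant negative cluster; and within that cluster a
*higher* SMD score tracks *lower* signal in the highest-MMSE tertile
(r = −0.91) but *higher* signal in the lowest tertile (r = +0.92), with no
association in the middle tertile — the opposite-sign pattern across
disease stages.

`analysis/02_awareness_group_stats.R` prints the behavioural side: mean
delta falls from controls/SCD through MCI to dementia, and the percentage
of participants with a negative delta rises from 46.3% (controls) and
25.0% (SCD) to 71.7% (MCI) and 89.2% (dementia) in a simulated cohort —
the progressive loss of memory awareness.

## Repository layout

```
R/                  package code: cohort/volume I/O, synthetic generator,
                    w-scores, group stats, voxelwise GLM engine,
                    cluster inference, pipeline, experiments
analysis/           numbered study drivers writing tables under results/
scripts/acceptance.R  family-wise error measurement (see above)
tests/testthat/     unit, property and end-to-end statistical tests
vignettes/          methods vignette: models, assumptions, design choices
```
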