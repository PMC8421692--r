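#!/usr/bin/env Rscript
# End-to-end voxelwise run on synthetic volumes with the planted
# stage-dependent sign switch: per-group SMD regressions, the SMD-by-MMSE
# interaction, Monte-Carlo cluster-extent inference and tertile-stratified
# correlations in the detected cluster.

library(awaremap)

mask <- array(TRUE, c(24L, 24L, 24L))
region <- array(FALSE, c(24L, 24L, 24L))
region[10:15, 10:15, 10:15] <- TRUE

cfg <- run_config(
  cohort = cohort_spec(seed = 1L), # sizes 67/36/60/37, shipped distributions
  effect = effect_spec(region,
                       slope_by_stratum = c(high = -0.8, low = 0.8),
                       noise_sd = 1, smoothing_fwhm_vox = 3, seed = 1L),
  mask = mask,
  moderator = "mmse",
  voxel_p = 0.005, alpha = 0.05, connectivity = 18, n_iter = 1000L,
  seed = 2026L)

manifest <- run_pipeline(cfg, "results/pipeline")

cat("\nPipeline manifest highlights:\n")
cat("  participants:", manifest$n_participants, "\n")
cat("  per-group maps:", paste(manifest$groups_fit, collapse = ", "), "\n")
cat("  residual FWHM (vox):",
    paste(round(manifest$fwhm_vox, 2), collapse = " x "), "\n")
cat("  k_min:", manifest$k_min, "voxels\n")
cat("  significant clusters per map/direction:\n")
print(manifest$significant_clusters)

tc <- utils::read.delim("results/pipeline/tertile_correlations.tsv")
cat("\nExtracted-cluster correlations with the SMD w-score by MMSE tertile:\n")
print(tc, digits = 3)
cat("\nFinding: the negative SMD-by-MMSE interaction cluster overlaps the\n",
    "planted region, with a negative correlation in the highest MMSE tertile\n",
    "and a positive one in the lowest - the opposite-sign pattern across\n",
    "disease stages.\n")
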