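#!/usr/bin/env Rscript
# Verify family-wise error control of the full voxelwise pipeline on
# pure-noise datasets: 200 null datasets, n = 60, 24x24x24 mask, noise
# smoothed to FWHM 3 voxels, voxel p < 0.005, corrected alpha 0.05.

library(awaremap)

res <- suppressMessages(fwer_null_experiment(
  n_datasets = 200L, n = 60L, mask_dim = c(24L, 24L, 24L), fwhm_vox = 3,
  voxel_p = 0.005, alpha = 0.05, n_iter_sim = 1000L, seed = 2026L))

dir.create("results", showWarnings = FALSE)
utils::write.table(res$per_dataset, "results/fwer_per_dataset.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)

cat(sprintf("Median residual smoothness: %.2f voxels FWHM\n", res$fwhm_median))
cat(sprintf("Monte-Carlo minimum cluster size: %d voxels\n", res$k_min))
cat(sprintf("Empirical FWER: %.3f (%d/%d null datasets with a significant cluster)\n",
            res$fwer, res$n_significant, res$n_datasets))
cat("Reference: nominal alpha 0.05; two binomial SEs allow up to 0.081.\n")
cat("Wrote results/fwer_per_dataset.tsv\n")
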