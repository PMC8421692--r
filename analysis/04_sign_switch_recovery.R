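#!/usr/bin/env Rscript
# Replicate the sign-switch recovery across independent simulations: planted
# slopes -0.8 (high-MMSE stratum) and +0.8 (low stratum), noise SD 1,
# 60 participants per stratum, 10 seeds.

library(awaremap)

res <- sign_switch_experiment(n_seeds = 10L, n_per_stratum = 60L,
                              slope_high = -0.8, slope_low = 0.8,
                              noise_sd = 1, seed = 2026L)

dir.create("results", showWarnings = FALSE)
utils::write.table(res$per_seed, "results/sign_switch_recovery.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)

cat("Per-seed recovery (Dice vs planted region; tertile correlations):\n")
print(res$per_seed, digits = 3)
cat(sprintf("\n%d/%d seeds recovered a significant negative-interaction cluster\n",
            res$n_success, res$n_seeds))
cat("with Dice >= 0.3 and opposite-sign tertile correlations.\n")
cat("Wrote results/sign_switch_recovery.tsv\n")
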