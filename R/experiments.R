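#' Family-wise error experiment on null synthetic datasets
#'
#' Measures the empirical family-wise error rate of the full voxelwise
#' pipeline: for each of `n_datasets` independent null datasets (no planted
#' effect anywhere), a cohort is simulated, SMD w-scores computed, smoothed
#' pure-noise volumes generated, the voxelwise regression of the volumes on
#' the SMD w-score (with age/sex/education covariates) fitted, and the
#' resulting t-map thresholded one-sided at `voxel_p` with the minimum
#' cluster size derived once for the dataset family by Monte-Carlo
#' simulation at the family's median residual smoothness. The returned
#' `fwer` is the fraction of datasets with at least one significant cluster;
#' it should not exceed `alpha` beyond binomial error.
#'
#' @param n_datasets number of independent null datasets.
#' @param n participants per dataset.
#' @param mask_dim 3-D grid (mask = full box).
#' @param fwhm_vox smoothing FWHM of the generated noise, in voxels.
#' @param voxel_p,alpha cluster-forming threshold and corrected alpha.
#' @param n_iter_sim Monte-Carlo iterations for the cluster-size simulation.
#' @param connectivity 6, 18 or 26.
#' @param direction side of the t-map tested (the calibration is one-sided).
#' @param seed master seed; all per-dataset seeds derive from it.
#' @return list: `fwer`, `n_significant`, `k_min`, `fwhm_median`,
#'   `per_dataset` data frame.
#' @export
fwer_null_experiment <- function(n_datasets = 200L, n = 60L,
                                 mask_dim = c(24L, 24L, 24L), fwhm_vox = 3,
                                 voxel_p = 0.005, alpha = 0.05,
                                 n_iter_sim = 1000L, connectivity = 18,
                                 direction = "negative", seed = 1L) {
  set.seed(seed)
  ds_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_datasets),
                     ncol = 2L)
  sim_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  mask <- array(TRUE, mask_dim)
  null_effect_region <- array(FALSE, mask_dim)

  tmaps <- vector("list", n_datasets)
  fwhm_est <- numeric(n_datasets)
  df_resid <- NA_integer_
  for (d in seq_len(n_datasets)) {
    spec <- cohort_spec(n = c(control = n, scd = 0, mci = 0, dementia = 0),
                        seed = ds_seeds[d, 1L])
    cohort <- generate_cohort(spec)
    aware <- compute_awareness(cohort)
    smd_w <- setNames(aware$smd_w, aware$participant_id)
    eff <- effect_spec(null_effect_region, slope_by_stratum = 0,
                       noise_sd = 1, smoothing_fwhm_vox = fwhm_vox,
                       seed = ds_seeds[d, 2L])
    stack <- generate_volumes(cohort, smd_w, eff, mask)
    design <- build_design(cohort, smd_w)
    fit <- fit_voxelwise(stack, design)
    tmaps[[d]] <- fit
    sm <- estimate_fwhm(fit$residuals, mask)
    pos <- sm$fwhm_vox[sm$fwhm_vox > 0]
    fwhm_est[d] <- if (length(pos) == 0L) 0 else exp(mean(log(pos)))
    df_resid <- fit$df_resid
  }

  fwhm_med <- median(fwhm_est)
  thresh <- simulate_cluster_threshold(
    mask, fwhm_med, voxel_p = voxel_p, corrected_alpha = alpha,
    n_iter = n_iter_sim, connectivity = connectivity, seed = sim_seed)

  any_sig <- logical(n_datasets)
  n_clusters <- integer(n_datasets)
  for (d in seq_len(n_datasets)) {
    rep <- threshold_and_cluster(tmaps[[d]], thresh, direction)
    any_sig[d] <- any(rep$clusters$status == "significant")
    n_clusters[d] <- nrow(rep$clusters)
  }
  list(
    fwer = mean(any_sig),
    n_significant = sum(any_sig),
    n_datasets = n_datasets,
    k_min = thresh$k_min,
    fwhm_median = fwhm_med,
    df_resid = df_resid,
    per_dataset = data.frame(dataset = seq_len(n_datasets),
                             fwhm = fwhm_est, any_significant = any_sig,
                             n_suprathreshold_clusters = n_clusters)
  )
}

#' Sign-switch recovery experiment
#'
#' Plants the stage-dependent, opposite-sign association — a negative slope
#' of voxel value on the SMD w-score in the high-MMSE stratum and a positive
#' slope in the low stratum — and checks that the full pipeline recovers it:
#' the SMD-by-MMSE interaction t-map must contain a significant
#' negative-direction cluster overlapping the planted region (Dice), and the
#' correlations between extracted cluster means and the SMD w-score must have
#' opposite signs in the top and bottom MMSE tertiles.
#'
#' @param n_seeds number of independent replicates.
#' @param n_per_stratum participants per clinical group (three groups with
#'   well-separated MMSE distributions, so MMSE tertiles track groups).
#' @param mask_dim 3-D grid (mask = full box).
#' @param region_halfwidth planted region is a centred cube of side
#'   `2 * region_halfwidth`.
#' @param slope_high,slope_low planted slopes in the high/low MMSE strata.
#' @param noise_sd,fwhm_vox noise level and smoothness of the volumes.
#' @param voxel_p,alpha,n_iter_sim,connectivity cluster inference settings.
#' @param dice_min Dice overlap against the planted region counted a success.
#' @param seed master seed.
#' @return list: `n_success`, `n_seeds`, `per_seed` data frame (dice,
#'   r_low, r_high, success).
#' @export
sign_switch_experiment <- function(n_seeds = 10L, n_per_stratum = 60L,
                                   mask_dim = c(24L, 24L, 24L),
                                   region_halfwidth = 3L,
                                   slope_high = -0.8, slope_low = 0.8,
                                   noise_sd = 1, fwhm_vox = 3,
                                   voxel_p = 0.005, alpha = 0.05,
                                   n_iter_sim = 1000L, connectivity = 18,
                                   dice_min = 0.3, seed = 1L) {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3L * n_seeds),
                  ncol = 3L)
  mask <- array(TRUE, mask_dim)
  ctr <- floor(mask_dim / 2)
  region <- array(FALSE, mask_dim)
  region[(ctr[1] - region_halfwidth + 1):(ctr[1] + region_halfwidth),
         (ctr[2] - region_halfwidth + 1):(ctr[2] + region_halfwidth),
         (ctr[3] - region_halfwidth + 1):(ctr[3] + region_halfwidth)] <- TRUE

  res <- data.frame(seed_idx = seq_len(n_seeds), dice = NA_real_,
                    r_low = NA_real_, r_high = NA_real_, success = FALSE)
  for (i in seq_len(n_seeds)) {
    spec <- cohort_spec(
      n = c(control = n_per_stratum, scd = 0, mci = n_per_stratum,
            dementia = n_per_stratum),
      seed = seeds[i, 1L])
    cohort <- generate_cohort(spec)
    aware <- compute_awareness(cohort)
    smd_w <- setNames(aware$smd_w, aware$participant_id)
    eff <- effect_spec(region,
                       slope_by_stratum = c(high = slope_high,
                                            low = slope_low),
                       noise_sd = noise_sd, smoothing_fwhm_vox = fwhm_vox,
                       seed = seeds[i, 2L])
    stack <- generate_volumes(cohort, smd_w, eff, mask)
    mmse <- setNames(cohort$mmse, cohort$participant_id)
    fit <- fit_interaction(stack, cohort, smd_w, mmse)
    sm <- estimate_fwhm(fit$residuals, mask)
    thresh <- simulate_cluster_threshold(
      mask, sm, voxel_p = voxel_p, corrected_alpha = alpha,
      n_iter = n_iter_sim, connectivity = connectivity,
      seed = seeds[i, 3L])
    rep <- threshold_and_cluster(fit, thresh, "negative")
    sig <- rep$clusters[rep$clusters$status == "significant", , drop = FALSE]
    if (nrow(sig) == 0L) next
    res$dice[i] <- dice_overlap(significant_voxels(rep), region)
    cid <- sig$cluster_id[which.max(sig$n_voxels)]
    extracted <- extract_cluster_means(stack, rep$labels, cid)
    strata <- tertile_split(cohort$mmse)
    sc <- stratified_correlations(extracted[cohort$participant_id], smd_w,
                                  strata)
    res$r_low[i] <- sc$r[sc$stratum == "low"]
    res$r_high[i] <- sc$r[sc$stratum == "high"]
    res$success[i] <- isTRUE(res$dice[i] >= dice_min &&
                               res$r_high[i] < 0 && res$r_low[i] > 0)
  }
  list(n_success = sum(res$success), n_seeds = n_seeds, per_seed = res)
}

#' Delta-score group-pattern experiment
#'
#' Simulates cohorts from the shipped score distributions and checks the
#' qualitative awareness pattern: the mean delta score decreases from
#' controls/SCD to MCI to dementia, and the percentage of participants with a
#' negative delta (underestimation, the anosognosia direction) is highest in
#' the dementia group.
#'
#' @param n_seeds number of independent replicates.
#' @param n_per_group participants per clinical group.
#' @param seed master seed.
#' @return list: `n_success`, `n_seeds`, `per_seed` data frame with group
#'   mean deltas, percent-negative values and the per-seed verdict.
#' @export
delta_pattern_experiment <- function(n_seeds = 10L, n_per_group = 200L,
                                     seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_seeds)
  res <- data.frame(seed_idx = seq_len(n_seeds),
                    delta_control = NA_real_, delta_scd = NA_real_,
                    delta_mci = NA_real_, delta_dementia = NA_real_,
                    pctneg_control = NA_real_, pctneg_scd = NA_real_,
                    pctneg_mci = NA_real_, pctneg_dementia = NA_real_,
                    success = FALSE)
  for (i in seq_len(n_seeds)) {
    spec <- cohort_spec(n = c(control = n_per_group, scd = n_per_group,
                              mci = n_per_group, dementia = n_per_group),
                        seed = seeds[i])
    aware <- compute_awareness(generate_cohort(spec))
    mu <- tapply(aware$delta, aware$group, mean)
    pneg <- tapply(aware$delta_sign == "negative", aware$group, mean) * 100
    res[i, 2:5] <- as.numeric(mu[GROUP_LEVELS])
    res[i, 6:9] <- as.numeric(pneg[GROUP_LEVELS])
    decreasing <- min(mu[["control"]], mu[["scd"]]) > mu[["mci"]] &&
      mu[["mci"]] > mu[["dementia"]]
    dem_highest <- pneg[["dementia"]] == max(pneg)
    res$success[i] <- decreasing && dem_highest
  }
  list(n_success = sum(res$success), n_seeds = n_seeds, per_seed = res)
}
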