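test_that("identical seeds give bit-identical cohorts and volumes", {
  spec <- cohort_spec(n = c(control = 12, scd = 5, mci = 6, dementia = 5),
                      seed = 99)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)

  mask <- array(TRUE, c(6, 6, 6))
  region <- array(FALSE, c(6, 6, 6)); region[3:4, 3:4, 3:4] <- TRUE
  w <- setNames(rnorm(nrow(c1)), c1$participant_id)
  eff <- effect_spec(region, slope_by_stratum = -0.5, seed = 7)
  s1 <- generate_volumes(c1, w, eff, mask)
  s2 <- generate_volumes(c1, w, eff, mask)
  expect_identical(s1$data, s2$data)
})

test_that("degenerate spec values behave as stated", {
  # no controls requested -> cohort without controls
  co <- generate_cohort(cohort_spec(n = c(control = 0, scd = 4, mci = 4,
                                          dementia = 4), seed = 1))
  expect_identical(sum(co$group == "control"), 0L)
  expect_identical(nrow(co), 12L)

  # all SDs zero -> every participant sits exactly at the group means
  spec0 <- cohort_spec(
    n = c(control = 5, scd = 0, mci = 5, dementia = 0),
    age = list(mean = rep(70, 4), sd = rep(0, 4)),
    education = list(mean = rep(12, 4), sd = rep(0, 4)),
    mmse = list(mean = c(29, 29, 26, 20), sd = rep(0, 4)),
    smd = list(mean = c(8, 13, 14, 15), sd = rep(0, 4)),
    objmem = list(mean = c(12, 11, 6, 2), sd = rep(0, 4)),
    seed = 3)
  co0 <- generate_cohort(spec0)
  expect_true(all(co0$age == 70))
  expect_true(all(co0$mmse[co0$group == "mci"] == 26))
  expect_true(all(co0$smd_raw[co0$group == "control"] == 8))

  # negative SD is a spec error
  expect_error(cohort_spec(age = list(mean = rep(70, 4), sd = c(-1, 1, 1, 1))),
               "sd must be >= 0")
})

test_that("group moments converge to the specification at large n", {
  spec <- cohort_spec(n = c(control = 10000, scd = 0, mci = 0, dementia = 0),
                      smd_objmem_cor = 0.4, seed = 123)
  co <- generate_cohort(spec)
  # MMSE is clipped to [0, 30]; the sample mean converges to the clipped-
  # normal mean, computed analytically here as the oracle
  mu <- 28.95; sdv <- 1.04
  c_hi <- (30 - mu) / sdv
  clipped_mean <- mu - sdv * (dnorm(c_hi) - c_hi * pnorm(c_hi, lower.tail = FALSE))
  expect_lt(abs(mean(co$mmse) - clipped_mean), 0.05)
  expect_lt(abs(mean(co$mmse) - 28.95), 0.15)
  expect_lt(abs(mean(co$age) - 70.10), 0.2)
  expect_lt(abs(sd(co$smd_raw) - 4), 0.15)
  expect_lt(abs(cor(co$smd_raw, co$objmem_raw) - 0.4), 0.03)
  expect_lt(abs(mean(co$sex == "female") - 0.537), 0.02)
})

test_that("noiseless planted slope is recovered exactly by per-voxel regression", {
  co <- make_test_cohort()
  aware <- compute_awareness(co)
  w <- setNames(aware$smd_w, aware$participant_id)
  mask <- array(TRUE, c(5, 5, 5))
  region <- array(FALSE, c(5, 5, 5)); region[2:4, 2:4, 2:4] <- TRUE
  eff <- effect_spec(region, slope_by_stratum = -1, noise_sd = 1e-8,
                     smoothing_fwhm_vox = 0, seed = 5)
  st <- generate_volumes(co, w, eff, mask)
  fit <- fit_voxelwise(st, build_design(co, w))
  expect_lt(max(abs(fit$beta[region] + 1)), 1e-6)
  expect_lt(max(abs(fit$beta[!region])), 1e-6)
  expect_gt(min(abs(fit$t[region])), 1e4)
})

test_that("a planted pure interaction flips the per-voxel SMD slope across MMSE tertiles", {
  spec <- cohort_spec(n = c(control = 30, scd = 0, mci = 30, dementia = 30),
                      seed = 21)
  co <- generate_cohort(spec)
  aware <- compute_awareness(co)
  w <- setNames(aware$smd_w, aware$participant_id)
  mask <- array(TRUE, c(6, 6, 6))
  region <- array(FALSE, c(6, 6, 6)); region[3:4, 3:4, 3:4] <- TRUE
  eff <- effect_spec(region, slope_by_stratum = 0,
                     interaction_coefficient = -0.3, noise_sd = 0.2,
                     smoothing_fwhm_vox = 0, seed = 22)
  st <- generate_volumes(co, w, eff, mask)
  strata <- tertile_split(co$mmse)
  # brute-force per-voxel least squares within tertile subsamples
  slope_in <- function(stratum) {
    idx <- which(strata == stratum)
    flat <- matrix(st$data[idx, , , ], length(idx), prod(dim(mask)))
    vox <- which(region)
    mean(vapply(vox, function(v) coef(lm(flat[, v] ~ w[idx]))[2], numeric(1)))
  }
  s_hi <- slope_in("high"); s_lo <- slope_in("low")
  expect_lt(s_hi, 0) # high MMSE centred positive -> negative product slope
  expect_gt(s_lo, 0)
})

test_that("with no planted effect the region is statistically indistinguishable from background", {
  spec <- cohort_spec(n = c(control = 50, scd = 0, mci = 0, dementia = 0),
                      seed = 31)
  co <- generate_cohort(spec)
  aware <- compute_awareness(co)
  w <- setNames(aware$smd_w, aware$participant_id)
  mask <- array(TRUE, c(8, 8, 8))
  region <- array(FALSE, c(8, 8, 8)); region[3:6, 3:6, 3:6] <- TRUE
  eff <- effect_spec(region, slope_by_stratum = 0, noise_sd = 1,
                     smoothing_fwhm_vox = 0, seed = 32)
  st <- generate_volumes(co, w, eff, mask)
  flat <- matrix(st$data, nrow(co), prod(dim(mask)))
  cors <- as.numeric(cor(w[co$participant_id], flat))
  ks <- suppressWarnings(stats::ks.test(cors[which(region)],
                                        cors[which(!region)]))
  expect_gt(ks$p.value, 0.01)
})

test_that("per-voxel type-I error at the cluster-forming threshold is nominal", {
  spec <- cohort_spec(n = c(control = 60, scd = 0, mci = 0, dementia = 0),
                      seed = 41)
  co <- generate_cohort(spec)
  aware <- compute_awareness(co)
  w <- setNames(aware$smd_w, aware$participant_id)
  mask <- array(TRUE, c(12, 12, 12)) # 1728 independent voxels at FWHM 0
  eff <- effect_spec(array(FALSE, c(12, 12, 12)), slope_by_stratum = 0,
                     noise_sd = 1, smoothing_fwhm_vox = 0, seed = 42)
  st <- generate_volumes(co, w, eff, mask)
  fit <- fit_voxelwise(st, build_design(co, w))
  p_hit <- mean(fit$t[mask] > qt(0.995, fit$df_resid))
  n_vox <- sum(mask)
  se <- sqrt(0.005 * 0.995 / n_vox)
  expect_lt(abs(p_hit - 0.005), 3.5 * se + 1e-9)
})

test_that("planting a region outside the mask is rejected", {
  co <- make_test_cohort()
  w <- setNames(rep(0, nrow(co)), co$participant_id)
  mask <- array(FALSE, c(4, 4, 4)); mask[1:2, , ] <- TRUE
  region <- array(FALSE, c(4, 4, 4)); region[4, 4, 4] <- TRUE
  eff <- effect_spec(region, seed = 1)
  expect_error(generate_volumes(co, w, eff, mask), "inside the mask")
})
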