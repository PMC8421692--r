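test_that("vectorized engine equals independent per-voxel regressions", {
  set.seed(20)
  co <- make_test_cohort()
  aware <- compute_awareness(co)
  w <- setNames(aware$smd_w, aware$participant_id)
  for (rep_i in 1:5) {
    data <- array(rnorm(14 * 4 * 4 * 4), c(14, 4, 4, 4))
    st <- make_stack(data, ids = co$participant_id)
    design <- build_design(co, w)
    fit <- fit_voxelwise(st, design)
    X <- design$X
    tcol <- match("smd_w", colnames(X))
    for (v in sample(64, 12)) {
      ijk <- arrayInd(v, c(4, 4, 4))
      y <- data[, ijk[1], ijk[2], ijk[3]]
      o <- oracle_voxel_fit(y, X, tcol)
      expect_lt(abs(fit$beta[v] - o["beta"]), 1e-8)
      expect_lt(abs(fit$t[v] - o["t"]), 1e-8)
    }
    expect_identical(fit$df_resid, 14L - ncol(X))
  }
})

test_that("permuting participant order leaves the t-map unchanged", {
  set.seed(21)
  co <- make_test_cohort()
  aware <- compute_awareness(co)
  w <- setNames(aware$smd_w, aware$participant_id)
  data <- array(rnorm(14 * 3 * 3 * 3), c(14, 3, 3, 3))
  st <- make_stack(data, ids = co$participant_id)
  fit1 <- fit_voxelwise(st, build_design(co, w))
  perm <- sample(14)
  st2 <- volume_stack(data[perm, , , , drop = FALSE], st$mask,
                      co$participant_id[perm])
  fit2 <- fit_voxelwise(st2, build_design(co, w)) # design order unchanged
  expect_equal(fit1$t, fit2$t, tolerance = 1e-10)
})

test_that("t-maps are invariant under outcome and regressor rescaling", {
  set.seed(22)
  co <- make_test_cohort()
  aware <- compute_awareness(co)
  w <- setNames(aware$smd_w, aware$participant_id)
  data <- array(rnorm(14 * 3 * 3 * 3), c(14, 3, 3, 3))
  st <- make_stack(data, ids = co$participant_id)
  t0 <- fit_voxelwise(st, build_design(co, w))$t
  st_scaled <- volume_stack(data * 7.3, st$mask, co$participant_id)
  expect_equal(fit_voxelwise(st_scaled, build_design(co, w))$t, t0,
               tolerance = 1e-9)
  expect_equal(fit_voxelwise(st, build_design(co, w * 0.25))$t, t0,
               tolerance = 1e-9)
})

test_that("degenerate designs and undersized samples are rejected", {
  co <- make_test_cohort()
  aware <- compute_awareness(co)
  w <- setNames(aware$smd_w, aware$participant_id)
  data <- array(rnorm(14 * 8), c(14, 2, 2, 2))
  st <- make_stack(data, ids = co$participant_id)
  const_mod <- setNames(rep(27, 14), co$participant_id)
  expect_error(
    fit_voxelwise(st, build_design(co, w, moderator = const_mod,
                                   interaction = TRUE)),
    "rank deficient.*moderator")
  tiny <- cohort_table(as.data.frame(co)[1:6, ])
  st6 <- make_stack(data[1:6, , , , drop = FALSE], ids = tiny$participant_id)
  expect_error(fit_voxelwise(st6, build_design(tiny, w[1:6])),
               "sample too small")
})

test_that("tertile splits follow rank thirds and the fixed MMSE cutpoints", {
  expect_identical(as.character(tertile_split(1:9)),
                   rep(c("low", "mid", "high"), each = 3))
  # tied boundary values fall entirely in the lower stratum
  s <- tertile_split(c(1, 2, 3, 3, 3, 5, 6, 7, 8))
  expect_identical(sum(s == "low"), 5L)
  # fixed cutpoints: high > 28, low < 27
  f <- tertile_split(c(30, 29, 28, 27, 26), mode = "fixed")
  expect_identical(as.character(f), c("high", "high", "mid", "mid", "low"))
  expect_error(tertile_split(rep(27, 6)), "distinct")
})

test_that("cluster means average exactly the cluster's voxels per participant", {
  data <- array(0, c(3, 3, 3, 1))
  data[, 1, 1, 1] <- c(1, 10, 100)
  data[, 2, 1, 1] <- c(3, 30, 300)
  data[, 3, 3, 1] <- c(7, 7, 7)
  st <- make_stack(data)
  labels <- array(0L, c(3, 3, 1))
  labels[1:2, 1, 1] <- 1L
  labels[3, 3, 1] <- 2L
  expect_equal(unname(extract_cluster_means(st, labels, 1L)), c(2, 20, 200))
  expect_equal(unname(extract_cluster_means(st, labels, 2L)), c(7, 7, 7))
  uniform <- make_stack(array(4.5, c(2, 3, 3, 1)))
  expect_equal(unname(extract_cluster_means(uniform, labels, 1L)), c(4.5, 4.5))
  expect_error(extract_cluster_means(st, labels, 9L), "not present")
})

test_that("the interaction t is negative in the planted region and null elsewhere", {
  n_neg <- 0L
  for (seed_i in 1:3) {
    spec <- cohort_spec(n = c(control = 20, scd = 0, mci = 20, dementia = 20),
                        seed = 500 + seed_i)
    co <- generate_cohort(spec)
    aware <- compute_awareness(co)
    w <- setNames(aware$smd_w, aware$participant_id)
    mask <- array(TRUE, c(8, 8, 8))
    region <- array(FALSE, c(8, 8, 8)); region[3:6, 3:6, 3:6] <- TRUE
    eff <- effect_spec(region, slope_by_stratum = 0,
                       interaction_coefficient = -0.2, noise_sd = 1,
                       smoothing_fwhm_vox = 0, seed = 600 + seed_i)
    st <- generate_volumes(co, w, eff, mask)
    mmse <- setNames(co$mmse, co$participant_id)
    fit <- fit_interaction(st, co, w, mmse)
    if (mean(fit$t[region]) < 0) n_neg <- n_neg + 1L
    expect_lt(abs(mean(fit$t[!region])), 0.5) # null background, n = 60
  }
  expect_gte(n_neg, 2L)
})

test_that("per-group fits produce one map per sufficiently large group", {
  spec <- cohort_spec(n = c(control = 10, scd = 9, mci = 10, dementia = 4),
                      seed = 61)
  co <- generate_cohort(spec)
  aware <- compute_awareness(co)
  w <- setNames(aware$smd_w, aware$participant_id)
  eff <- effect_spec(array(FALSE, c(4, 4, 4)), slope_by_stratum = 0,
                     smoothing_fwhm_vox = 0, seed = 62)
  st <- generate_volumes(co, w, eff, array(TRUE, c(4, 4, 4)))
  suppressMessages(maps <- fit_per_group(st, co, w, min_n = 8L))
  expect_setequal(names(maps), c("control", "scd", "mci")) # dementia too small
  expect_identical(maps$control$n, 10L)
})
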