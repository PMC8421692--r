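test_that("component labelling matches the transitive-closure oracle on random arrays", {
  set.seed(30)
  for (i in 1:100) {
    dm <- sample(2:6, 3, replace = TRUE)
    binary <- array(runif(prod(dm)) < 0.35, dm)
    conn <- sample(c(6, 18, 26), 1)
    got <- label_components(binary, conn)
    want <- oracle_components(binary, conn)
    expect_identical(sort(got$sizes), sort(want$sizes))
    if (length(want$sizes) > 0) {
      # identical partition: same-label relation must agree pairwise
      got_m <- got$labels[binary]
      idx <- which(binary)
      ord <- match(idx, (want$coords[, 3] - 1) * dm[1] * dm[2] +
                     (want$coords[, 2] - 1) * dm[1] + want$coords[, 1])
      want_m <- want$membership[ord]
      expect_identical(outer(got_m, got_m, "=="), outer(want_m, want_m, "=="))
    }
  }
})

test_that("edge-diagonal voxels merge at connectivity 18 but not 6", {
  b <- array(FALSE, c(3, 3, 3))
  b[1, 1, 1] <- TRUE
  b[2, 2, 1] <- TRUE # differs in two coordinates: edge neighbour
  expect_identical(length(label_components(b, 6)$sizes), 2L)
  expect_identical(length(label_components(b, 18)$sizes), 1L)
  b2 <- array(FALSE, c(3, 3, 3))
  b2[1, 1, 1] <- TRUE
  b2[2, 2, 2] <- TRUE # corner neighbour: merges only at 26
  expect_identical(length(label_components(b2, 18)$sizes), 2L)
  expect_identical(length(label_components(b2, 26)$sizes), 1L)
})

test_that("white-noise residuals yield near-zero FWHM and smoothing is recovered", {
  set.seed(31)
  res_white <- array(rnorm(8 * 16^3), c(8, 16, 16, 16))
  sm <- estimate_fwhm(res_white, array(TRUE, c(16, 16, 16)))
  expect_true(all(sm$fwhm_vox <= 1.2))

  # known kernel: sigma = 1.5 voxels -> FWHM = 3.532
  fwhm_true <- 1.5 * 2 * sqrt(2 * log(2))
  res_sm <- array(0, c(6, 24, 24, 24))
  for (v in 1:6) {
    res_sm[v, , , ] <- smooth_gaussian3d(array(rnorm(24^3), c(24, 24, 24)),
                                         fwhm_true)
  }
  est <- estimate_fwhm(res_sm, array(TRUE, c(24, 24, 24)))
  expect_true(all(abs(est$fwhm_vox - fwhm_true) / fwhm_true < 0.1))
})

test_that("replicated residual volumes pool to the single-volume estimate", {
  set.seed(32)
  vol <- smooth_gaussian3d(array(rnorm(12^3), c(12, 12, 12)), 2)
  mask <- array(TRUE, c(12, 12, 12))
  two <- array(0, c(2, 12, 12, 12)); for (v in 1:2) two[v, , , ] <- vol
  four <- array(0, c(4, 12, 12, 12)); for (v in 1:4) four[v, , , ] <- vol
  expect_equal(estimate_fwhm(two, mask)$fwhm_vox,
               estimate_fwhm(four, mask)$fwhm_vox, tolerance = 1e-12)
  expect_error(estimate_fwhm(array(0, c(1, 4, 4, 4)), array(TRUE, c(4, 4, 4))),
               "at least 2")
})

test_that("the two-voxel null threshold matches exact enumeration", {
  # two independent N(0,1) voxels, threshold z > 0 (voxel_p = 0.5):
  # P(max size >= 2) = 1/4, P(max >= 1) = 3/4
  mask <- array(FALSE, c(4, 1, 1)); mask[2:3, 1, 1] <- TRUE
  th_loose <- simulate_cluster_threshold(mask, 0, voxel_p = 0.5,
                                         corrected_alpha = 0.3,
                                         n_iter = 20000, seed = 33)
  expect_identical(th_loose$k_min, 2L)
  expect_false(th_loose$saturated)
  expect_lt(abs(mean(th_loose$null_max_sizes >= 2) - 0.25), 0.01)
  expect_lt(abs(mean(th_loose$null_max_sizes >= 1) - 0.75), 0.01)

  expect_warning(
    th_tight <- simulate_cluster_threshold(mask, 0, voxel_p = 0.5,
                                           corrected_alpha = 0.05,
                                           n_iter = 20000, seed = 33),
    "saturated")
  expect_identical(th_tight$k_min, 3L) # mask size + 1: unattainable
  expect_true(th_tight$saturated)
})

test_that("a degenerate voxel threshold saturates at the mask size", {
  mask <- array(TRUE, c(3, 3, 1))
  expect_warning(
    th <- simulate_cluster_threshold(mask, 0, voxel_p = 1.0, n_iter = 100,
                                     seed = 34),
    "degenerate")
  expect_identical(th$k_min, 9L)
  expect_true(th$saturated)
  expect_true(all(th$null_max_sizes == 9L))
})

test_that("k_min responds monotonically to alpha and smoothness", {
  mask <- array(TRUE, c(14, 14, 14))
  for (s in 1:5) {
    lo <- simulate_cluster_threshold(mask, 2, voxel_p = 0.01,
                                     corrected_alpha = 0.05, n_iter = 200,
                                     seed = 40 + s)
    hi <- simulate_cluster_threshold(mask, 2, voxel_p = 0.01,
                                     corrected_alpha = 0.2, n_iter = 200,
                                     seed = 40 + s)
    expect_gte(lo$k_min, hi$k_min) # tighter alpha cannot shrink k_min
    dbl <- simulate_cluster_threshold(mask, 4, voxel_p = 0.01,
                                      corrected_alpha = 0.05, n_iter = 200,
                                      seed = 40 + s)
    expect_gte(dbl$k_min, lo$k_min) # doubling FWHM cannot shrink k_min
  }
})

test_that("thresholding labels the printed suprathreshold pattern correctly", {
  # 4x4x1 t-map with a 3-voxel L-shape above the cut and one isolated voxel
  tmat <- matrix(0, 4, 4)
  tmat[1, 1] <- 4; tmat[2, 1] <- 3.8; tmat[2, 2] <- 3.5 # L-shape
  tmat[4, 4] <- 3.2                                      # isolated
  tmap <- structure(list(
    t = array(tmat, c(4, 4, 1)), beta = array(0, c(4, 4, 1)),
    df_resid = 20L, residuals = NULL, mask = array(TRUE, c(4, 4, 1)),
    affine = diag(4), ids = NULL, target = "smd_w", model_label = "toy",
    n = 25L), class = "stat_map")
  thr <- structure(list(k_min = 2L, voxel_p = 0.005, corrected_alpha = 0.05,
                        null_max_sizes = integer(0), n_iter = 0L,
                        connectivity = 6L, fwhm_vox = rep(0, 3),
                        saturated = FALSE, seed = 1L),
                   class = "cluster_threshold")
  rep <- threshold_and_cluster(tmap, thr, "positive")
  expect_identical(nrow(rep$clusters), 2L)
  sig <- rep$clusters[rep$clusters$status == "significant", ]
  expect_identical(sig$n_voxels, 3L) # the L-shape
  expect_equal(sig$peak_t, 4)
  trend <- rep$clusters[rep$clusters$status == "trend", ]
  expect_identical(trend$n_voxels, 1L) # isolated voxel below k_min

  # negative direction finds nothing here
  rep_neg <- threshold_and_cluster(tmap, thr, "negative")
  expect_identical(nrow(rep_neg$clusters), 0L)

  # all-zero map: empty report either way
  tmap0 <- tmap; tmap0$t <- array(0, c(4, 4, 1))
  expect_identical(nrow(threshold_and_cluster(tmap0, thr, "positive")$clusters),
                   0L)
})

test_that("dice overlap and significant-voxel extraction behave as defined", {
  a <- array(FALSE, c(4, 4, 1)); a[1:2, 1, 1] <- TRUE
  b <- array(FALSE, c(4, 4, 1)); b[2:3, 1, 1] <- TRUE
  expect_equal(dice_overlap(a, b), 0.5)
  expect_equal(dice_overlap(a, a), 1)
})
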