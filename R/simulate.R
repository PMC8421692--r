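#' Specification of a synthetic cohort
#'
#' Per-group sample sizes and score distributions used by [generate_cohort()].
#' The shipped defaults follow the demographic and clinical profile of a
#' single-centre Alzheimer's-continuum cohort with four clinical groups
#' (controls, SCD, MCI, dementia): group sizes 67/36/60/37, MMSE means
#' 28.95/29.00/26.92/20.43, and age/education/female-fraction to match.
#' Subjective-complaint (`smd`) and objective-memory (`objmem`) raw-score
#' distributions are chosen so complaints are elevated in every patient group
#' and rise mildly along the continuum while objective memory declines from
#' controls/SCD to MCI to dementia, reproducing the qualitative group pattern
#' of complaint and performance scores.
#'
#' @param n named integer vector of group sizes (names: control, scd, mci,
#'   dementia).
#' @param age,education,mmse,smd,objmem each a list with numeric `mean` and
#'   `sd` vectors of length 4 (per group, in the order control/scd/mci/
#'   dementia).
#' @param female_fraction per-group probability a participant is female.
#' @param smd_objmem_cor within-group correlation between the two raw scores.
#' @param amyloid_fraction per-group probability of amyloid positivity; `NULL`
#'   omits the amyloid column.
#' @param sex_effect additive effect of male sex on (smd, objmem) raw scores;
#'   default zero so covariate adjustment can be tested with and without true
#'   sex signal.
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(
    n = c(control = 67, scd = 36, mci = 60, dementia = 37),
    age = list(mean = c(70.10, 67.47, 72.28, 68.38),
               sd = c(6.34, 7.51, 7.35, 10.05)),
    education = list(mean = c(12.33, 13.22, 11.48, 10.84),
                     sd = c(3.76, 3.59, 3.60, 3.10)),
    mmse = list(mean = c(28.95, 29.00, 26.92, 20.43),
                sd = c(1.04, 1.06, 1.80, 4.61)),
    smd = list(mean = c(8, 13, 14, 15), sd = c(4, 4, 5, 5)),
    objmem = list(mean = c(12, 11.5, 6, 2), sd = c(2.5, 2.5, 3, 3)),
    female_fraction = c(0.537, 0.444, 0.450, 0.405),
    smd_objmem_cor = 0,
    amyloid_fraction = c(0.25, 0.30, 0.60, 0.90),
    sex_effect = c(smd = 0, objmem = 0),
    seed = 1L) {
  n <- n[GROUP_LEVELS]
  n[is.na(n)] <- 0L
  names(n) <- GROUP_LEVELS
  check4 <- function(x, what) {
    if (length(x$mean) != 4L || length(x$sd) != 4L) {
      stop(what, " must have 4 per-group means and sds", call. = FALSE)
    }
    if (any(x$sd < 0)) stop(what, " sd must be >= 0", call. = FALSE)
    x
  }
  if (any(n < 0)) stop("sample sizes must be >= 0", call. = FALSE)
  ff <- rep_len(female_fraction, 4L)
  if (any(ff < 0 | ff > 1)) {
    stop("female_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (abs(smd_objmem_cor) > 1) {
    stop("smd_objmem_cor must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(
    n = n,
    age = check4(age, "age"), education = check4(education, "education"),
    mmse = check4(mmse, "mmse"), smd = check4(smd, "smd"),
    objmem = check4(objmem, "objmem"),
    female_fraction = ff,
    smd_objmem_cor = smd_objmem_cor,
    amyloid_fraction = if (is.null(amyloid_fraction)) NULL
                       else rep_len(amyloid_fraction, 4L),
    sex_effect = sex_effect,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws a seeded cohort from a [cohort_spec()]: age, education and MMSE are
#' Gaussian per group (MMSE clipped to \[0, 30\], education to >= 0), sex is
#' Bernoulli on the female fraction, and the subjective/objective raw memory
#' scores come from a bivariate normal with the specified within-group
#' correlation, plus any specified additive sex effect.
#'
#' @param spec a [cohort_spec()].
#' @return A [cohort_table()]; bit-identical for identical specs (same seed).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  rows <- vector("list", 4L)
  idx0 <- 0L
  for (g in seq_along(GROUP_LEVELS)) {
    ng <- spec$n[[g]]
    if (ng == 0L) next
    sex <- ifelse(rbinom(ng, 1L, spec$female_fraction[g]) == 1L,
                  "female", "male")
    male <- as.numeric(sex == "male")
    age <- rnorm(ng, spec$age$mean[g], spec$age$sd[g])
    edu <- pmax(rnorm(ng, spec$education$mean[g], spec$education$sd[g]), 0)
    mmse <- pmin(pmax(rnorm(ng, spec$mmse$mean[g], spec$mmse$sd[g]), 0), 30)
    z1 <- rnorm(ng); z2 <- rnorm(ng)
    rho <- spec$smd_objmem_cor
    smd <- spec$smd$mean[g] + spec$smd$sd[g] * z1 +
      spec$sex_effect[["smd"]] * male
    obj <- spec$objmem$mean[g] + spec$objmem$sd[g] *
      (rho * z1 + sqrt(1 - rho^2) * z2) +
      spec$sex_effect[["objmem"]] * male
    df <- data.frame(
      participant_id = sprintf("sub-%04d", idx0 + seq_len(ng)),
      group = GROUP_LEVELS[g], age = age, sex = sex, education = edu,
      mmse = mmse, smd_raw = smd, objmem_raw = obj,
      stringsAsFactors = FALSE
    )
    if (!is.null(spec$amyloid_fraction)) {
      df$amyloid_positive <- rbinom(ng, 1L, spec$amyloid_fraction[g]) == 1L
    }
    rows[[g]] <- df
    idx0 <- idx0 + ng
  }
  cohort_table(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
}

#' Specification of a planted voxelwise effect
#'
#' Describes the spatial structure planted by [generate_volumes()]: inside
#' `region`, voxel intensity follows a linear model in the participant's SMD
#' w-score with a stratum-dependent slope and an optional SMD-by-MMSE
#' interaction; everywhere in the mask, spatially smoothed Gaussian noise is
#' added.
#'
#' @param region 3-D logical array marking the planted cluster (must lie
#'   inside the analysis mask at generation time).
#' @param slope_by_stratum named numeric vector of signed slopes of voxel
#'   value on the SMD w-score; names are either MMSE tertile strata
#'   (`low`/`mid`/`high`) or clinical groups (`control`/`scd`/`mci`/
#'   `dementia`). A single unnamed value applies to everyone.
#' @param interaction_coefficient signed coefficient of
#'   `smd_w * (mmse - mean(mmse))`.
#' @param noise_sd marginal voxel SD of the smoothed noise (must be > 0).
#' @param smoothing_fwhm_vox Gaussian noise FWHM in voxels (scalar or
#'   per-axis length 3; >= 0).
#' @param baseline constant added inside the mask.
#' @param seed integer RNG seed.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(region, slope_by_stratum = 0,
                        interaction_coefficient = 0, noise_sd = 1,
                        smoothing_fwhm_vox = 3, baseline = 0, seed = 1L) {
  if (length(dim(region)) != 3L) stop("region must be 3-D", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  fwhm <- rep_len(as.numeric(smoothing_fwhm_vox), 3L)
  if (any(fwhm < 0)) stop("smoothing_fwhm_vox must be >= 0", call. = FALSE)
  structure(list(
    region = array(as.logical(region > 0), dim(region)),
    slope_by_stratum = slope_by_stratum,
    interaction_coefficient = interaction_coefficient,
    noise_sd = noise_sd, smoothing_fwhm_vox = fwhm,
    baseline = baseline, seed = as.integer(seed)
  ), class = "effect_spec")
}

#' Generate synthetic participant volumes with a planted effect
#'
#' Inside the planted region each voxel equals
#' `baseline + slope(stratum) * smd_w + interaction_coefficient * smd_w *
#' (mmse - mean(mmse))`; spatially smoothed Gaussian noise (circularly
#' convolved white noise rescaled so the marginal voxel SD equals `noise_sd`)
#' is added everywhere in the mask, and voxels outside the mask are zero.
#' Slopes are planted on the w-score scale so fitted coefficients are directly
#' comparable to planted ones.
#'
#' @param cohort a [cohort_table()].
#' @param wscores named numeric vector of SMD w-scores (names = participant
#'   ids) used as the planted regressor.
#' @param effect an [effect_spec()].
#' @param mask 3-D logical analysis mask.
#' @return A [volume_stack()]; bit-identical for identical inputs and seed.
#' @export
generate_volumes <- function(cohort, wscores, effect, mask) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(effect, "effect_spec"))
  mask <- array(as.logical(mask > 0), dim(mask))
  if (!identical(dim(effect$region), dim(mask))) {
    stop("region and mask grids differ", call. = FALSE)
  }
  if (any(effect$region & !mask)) {
    stop("planted region must lie inside the mask", call. = FALSE)
  }
  ids <- cohort$participant_id
  w <- wscores[ids]
  if (anyNA(w)) stop("missing SMD w-score for some participants", call. = FALSE)

  slopes <- effect$slope_by_stratum
  if (is.null(names(slopes)) && length(slopes) == 1L) {
    slope_i <- rep(slopes, nrow(cohort))
  } else if (all(names(slopes) %in% GROUP_LEVELS)) {
    slope_i <- unname(slopes[as.character(cohort$group)])
    slope_i[is.na(slope_i)] <- 0
  } else if (all(names(slopes) %in% c("low", "mid", "high"))) {
    strata <- tertile_split(cohort$mmse)
    full <- c(low = 0, mid = 0, high = 0)
    full[names(slopes)] <- slopes
    slope_i <- unname(full[strata])
  } else {
    stop("slope_by_stratum names must be clinical groups or low/mid/high",
         call. = FALSE)
  }
  mmse_c <- cohort$mmse - mean(cohort$mmse)
  amp <- slope_i * w + effect$interaction_coefficient * w * mmse_c

  set.seed(effect$seed)
  dm <- dim(mask)
  n <- nrow(cohort)
  data <- array(0, dim = c(n, dm))
  region_v <- effect$region
  for (i in seq_len(n)) {
    vol <- array(0, dm)
    vol[mask] <- effect$baseline
    vol[region_v] <- vol[region_v] + amp[i]
    noise <- smooth_noise_field(dm, effect$smoothing_fwhm_vox) * effect$noise_sd
    vol[mask] <- vol[mask] + noise[mask]
    data[i, , , ] <- vol
  }
  volume_stack(data, mask, ids)
}

# --- Gaussian smoothing primitives -----------------------------------------
#
# Smoothing is implemented as circular (periodic) convolution via circulant
# matrix products along each axis. Periodic wrapping keeps the smoothed field
# exactly stationary, so white noise smoothed and divided by the kernel L2
# norm has unit marginal SD at every voxel.

FWHM_SIGMA <- 2 * sqrt(2 * log(2)) # FWHM = 2.3548 sigma for a Gaussian kernel

gaussian_kernel1d <- function(fwhm) {
  if (fwhm <= 0) return(1)
  sigma <- fwhm / FWHM_SIGMA
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# circulant smoothing matrix for axis length n (kernel wrapped mod n)
circulant_kernel_matrix <- function(n, fwhm) {
  k <- gaussian_kernel1d(fwhm)
  r <- (length(k) - 1L) / 2L
  row0 <- numeric(n)
  for (m in seq_along(k)) {
    pos <- ((m - 1L - r) %% n) + 1L
    row0[pos] <- row0[pos] + k[m]
  }
  idx <- outer(seq_len(n), seq_len(n), function(i, j) ((i - j) %% n) + 1L)
  matrix(row0[idx], n, n)
}

#' Smooth a 3-D array with a separable Gaussian kernel
#'
#' Circular (periodic) convolution along each axis.
#'
#' @param arr 3-D numeric array.
#' @param fwhm_vox kernel FWHM in voxels (scalar or per-axis length 3).
#' @return Smoothed array of the same dimensions.
#' @export
smooth_gaussian3d <- function(arr, fwhm_vox) {
  dm <- dim(arr)
  stopifnot(length(dm) == 3L)
  fwhm <- rep_len(as.numeric(fwhm_vox), 3L)
  mats <- lapply(1:3, function(a) {
    if (fwhm[a] > 0) circulant_kernel_matrix(dm[a], fwhm[a]) else NULL
  })
  x <- arr
  if (!is.null(mats[[1L]])) {
    x <- array(mats[[1L]] %*% matrix(x, dm[1L], dm[2L] * dm[3L]), dm)
  }
  if (!is.null(mats[[2L]])) {
    xp <- aperm(x, c(2L, 1L, 3L))
    xp <- array(mats[[2L]] %*% matrix(xp, dm[2L], dm[1L] * dm[3L]),
                c(dm[2L], dm[1L], dm[3L]))
    x <- aperm(xp, c(2L, 1L, 3L))
  }
  if (!is.null(mats[[3L]])) {
    x <- array(matrix(x, dm[1L] * dm[2L], dm[3L]) %*% t(mats[[3L]]), dm)
  }
  x
}

# unit-marginal-SD smoothed white Gaussian noise field (uses current RNG state)
smooth_noise_field <- function(dm, fwhm_vox) {
  fwhm <- rep_len(as.numeric(fwhm_vox), 3L)
  noise <- array(rnorm(prod(dm)), dm)
  if (all(fwhm <= 0)) return(noise)
  sm <- smooth_gaussian3d(noise, fwhm)
  scale <- prod(vapply(1:3, function(a) {
    if (fwhm[a] <= 0) return(1)
    sqrt(sum(circulant_kernel_matrix(dm[a], fwhm[a])[1L, ]^2))
  }, numeric(1)))
  sm / scale
}
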