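connectivity_offsets <- function(connectivity = c("18", "6", "26")) {
  connectivity <- as.character(connectivity[1L])
  if (!connectivity %in% c("6", "18", "26")) {
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  }
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0 & off$dk == 0), ]
  ord <- abs(off$di) + abs(off$dj) + abs(off$dk)
  keep <- switch(connectivity,
                 "6" = ord == 1L,
                 "18" = ord <= 2L,
                 "26" = rep(TRUE, nrow(off)))
  as.matrix(off[keep, , drop = FALSE])
}

#' Label connected components of a 3-D binary array
#'
#' Breadth-first labelling under 6 (face), 18 (face+edge) or 26 (face+edge+
#' corner) connectivity. Labels are positive integers assigned in decreasing
#' order of component size (ties by discovery order).
#'
#' @param binary 3-D logical (or 0/1) array.
#' @param connectivity 6, 18 or 26 (default 18, the common SPM practice).
#' @return list with integer 3-D `labels` (0 = background) and integer vector
#'   `sizes` (voxels per label).
#' @export
label_components <- function(binary, connectivity = 18) {
  dm <- dim(binary)
  stopifnot(length(dm) == 3L)
  supra <- array(binary > 0, dm)
  labels <- array(0L, dm)
  seeds <- which(supra)
  if (length(seeds) == 0L) return(list(labels = labels, sizes = integer(0)))
  off <- connectivity_offsets(connectivity)
  n_off <- nrow(off)
  # linear-index step for each offset; validity still needs coordinate checks
  step <- off[, 1L] + off[, 2L] * dm[1L] + off[, 3L] * dm[1L] * dm[2L]
  lab <- 0L
  sizes <- integer(0)
  stack <- integer(length(seeds))
  for (s in seeds) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    labels[s] <- lab
    top <- 1L
    stack[1L] <- s
    csize <- 0L
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      csize <- csize + 1L
      k0 <- (v - 1L) %/% (dm[1L] * dm[2L])
      rem <- (v - 1L) %% (dm[1L] * dm[2L])
      j0 <- rem %/% dm[1L]
      i0 <- rem %% dm[1L]
      for (m in seq_len(n_off)) {
        i <- i0 + off[m, 1L]; j <- j0 + off[m, 2L]; k <- k0 + off[m, 3L]
        if (i < 0L || i >= dm[1L] || j < 0L || j >= dm[2L] ||
            k < 0L || k >= dm[3L]) next
        nb <- v + step[m]
        if (supra[nb] && labels[nb] == 0L) {
          labels[nb] <- lab
          top <- top + 1L
          stack[top] <- nb
        }
      }
    }
    sizes <- c(sizes, csize)
  }
  # relabel by decreasing size for stable reporting
  ord <- order(sizes, decreasing = TRUE)
  remap <- integer(length(sizes))
  remap[ord] <- seq_along(sizes)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  list(labels = labels, sizes = sizes[ord])
}

#' Estimate residual-field smoothness from standardized residuals
#'
#' Per-axis FWHM (in voxels) from the Gaussian-autocorrelation relation
#' `FWHM = sqrt(-2 log 2 / log(1 - var(D)/2))`, where `D` is the first
#' spatial difference of each standardized residual volume along that axis,
#' pooled over volumes and in-mask voxel pairs. Each residual volume is
#' standardized to zero mean and unit variance in-mask before differencing.
#' Autocorrelation ratios outside (0, 1) are clipped with a warning (at 0,
#' i.e. FWHM 0, from below; at a FWHM equal to the axis extent from above).
#'
#' @param residuals 4-D standardized residual stack (volumes x i x j x k),
#'   e.g. the `residuals` element of a `stat_map`.
#' @param mask 3-D logical analysis mask.
#' @return An object of class `smoothness_estimate`: `fwhm_vox` (length 3),
#'   `method`, `n_residual_volumes`.
#' @export
estimate_fwhm <- function(residuals, mask) {
  dm4 <- dim(residuals)
  stopifnot(length(dm4) == 4L)
  n_vol <- dm4[1L]
  if (n_vol < 2L) stop("need at least 2 residual volumes", call. = FALSE)
  dm <- dm4[2:4]
  mask <- array(mask > 0, dm)
  vox <- which(mask)
  flat <- matrix(residuals, n_vol, prod(dm))

  fwhm <- numeric(3L)
  for (axis in 1:3) {
    shift <- c(1L, dm[1L], dm[1L] * dm[2L])[axis]
    coord <- arrayInd(vox, dm)
    ok <- coord[, axis] < dm[axis]
    a <- vox[ok]
    b <- a + shift
    in_b <- mask[b]
    a <- a[in_b]; b <- b[in_b]
    if (length(a) == 0L) { fwhm[axis] <- 0; next }
    ss <- 0; nn <- 0
    for (v in seq_len(n_vol)) {
      row <- flat[v, vox]
      mu <- mean(row); sdv <- sd(row)
      if (!is.finite(sdv) || sdv == 0) next
      z <- (flat[v, ] - mu) / sdv
      d <- z[b] - z[a]
      ss <- ss + sum(d^2)
      nn <- nn + length(d)
    }
    if (nn == 0L) { fwhm[axis] <- 0; next }
    var_d <- ss / nn
    ratio <- 1 - var_d / 2
    ratio_max <- exp(-2 * log(2) / dm[axis]^2) # caps FWHM at the axis extent
    if (ratio >= ratio_max) {
      warning("autocorrelation ratio clipped on axis ", axis,
              "; residuals smoother than resolvable")
      ratio <- ratio_max
    }
    fwhm[axis] <- if (ratio <= 0) 0 else sqrt(-2 * log(2) / log(ratio))
  }
  structure(list(fwhm_vox = fwhm,
                 method = "first-difference Gaussian autocorrelation",
                 n_residual_volumes = n_vol),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("<smoothness_estimate> FWHM (vox): %s | %d residual volumes\n",
              paste(signif(x$fwhm_vox, 4), collapse = " x "),
              x$n_residual_volumes))
  invisible(x)
}

#' Monte-Carlo minimum cluster size for corrected inference
#'
#' Simulates smooth Gaussian null fields on the mask to find the minimum
#' cluster extent `k_min` such that the probability of observing any
#' suprathreshold cluster of at least `k_min` voxels is at most
#' `corrected_alpha`. Each iteration draws white Gaussian noise on the mask
#' bounding box, convolves it with the Gaussian kernel of the given FWHM,
#' restricts to the mask, and thresholds one-sided at
#' `z = qnorm(1 - voxel_p)`, recording the maximum connected component size.
#' The kernel scaling makes the smoothed field exactly unit-variance at every
#' voxel, so no empirical rescaling is applied (an empirical in-mask
#' standardization would couple voxels and distort the null on small masks).
#'
#' If no cluster size controls the FWER the result is flagged `saturated`:
#' `k_min` is the mask size plus one (no attainable cluster), or the mask
#' size itself in the fully degenerate `voxel_p >= 1` case where every voxel
#' is always suprathreshold.
#'
#' @param mask 3-D logical analysis mask (non-empty).
#' @param fwhm_vox smoothness in voxels; a length-3 estimate is reduced to
#'   its geometric mean and applied isotropically unless
#'   `anisotropic = TRUE`.
#' @param voxel_p cluster-forming (one-sided) voxel threshold, default 0.005.
#' @param corrected_alpha target family-wise alpha, default 0.05.
#' @param n_iter Monte-Carlo iterations (>= 100; 10,000 recommended for
#'   production use).
#' @param connectivity 6, 18 or 26.
#' @param seed integer RNG seed.
#' @param anisotropic use per-axis FWHM instead of the geometric mean.
#' @return An object of class `cluster_threshold`: `k_min`, `voxel_p`,
#'   `corrected_alpha`, `null_max_sizes`, `n_iter`, `connectivity`,
#'   `fwhm_vox`, `saturated`, `seed`.
#' @export
simulate_cluster_threshold <- function(mask, fwhm_vox, voxel_p = 0.005,
                                       corrected_alpha = 0.05,
                                       n_iter = 1000L, connectivity = 18,
                                       seed = 1L, anisotropic = FALSE) {
  if (inherits(fwhm_vox, "smoothness_estimate")) fwhm_vox <- fwhm_vox$fwhm_vox
  fwhm_vox <- as.numeric(fwhm_vox)
  if (any(fwhm_vox < 0)) stop("fwhm must be >= 0", call. = FALSE)
  if (n_iter < 100L) stop("n_iter must be >= 100", call. = FALSE)
  if (voxel_p <= 0) stop("voxel_p must be positive", call. = FALSE)
  mask <- array(mask > 0, dim(mask))
  n_mask <- sum(mask)
  if (n_mask == 0L) stop("mask is empty", call. = FALSE)
  if (!anisotropic && length(fwhm_vox) > 1L) {
    pos <- fwhm_vox[fwhm_vox > 0]
    fwhm_vox <- if (length(pos) == 0L) 0 else exp(mean(log(pos)))
  }
  fwhm3 <- rep_len(fwhm_vox, 3L)

  # crop to the mask bounding box; components cannot cross the mask boundary
  rng <- apply(which(mask, arr.ind = TRUE), 2L, range)
  sub <- mask[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
              drop = FALSE]
  sub <- array(sub, dim = c(
    rng[2, 1] - rng[1, 1] + 1L, rng[2, 2] - rng[1, 2] + 1L,
    rng[2, 3] - rng[1, 3] + 1L))
  dm <- dim(sub)
  in_sub <- which(sub)
  zcut <- qnorm(1 - min(voxel_p, 1))

  set.seed(seed)
  max_sizes <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    field <- smooth_noise_field(dm, fwhm3)
    supra <- array(FALSE, dm)
    supra[in_sub] <- field[in_sub] > zcut
    if (!any(supra)) { max_sizes[it] <- 0L; next }
    cc <- label_components(supra, connectivity)
    max_sizes[it] <- max(cc$sizes)
  }

  exceed <- function(k) mean(max_sizes >= k)
  k_min <- NA_integer_
  saturated <- FALSE
  for (k in seq_len(n_mask)) {
    if (exceed(k) <= corrected_alpha) { k_min <- k; break }
  }
  if (is.na(k_min)) {
    saturated <- TRUE
    if (voxel_p >= 1) {
      k_min <- n_mask
      warning("degenerate voxel threshold (voxel_p >= 1): every in-mask ",
              "voxel is suprathreshold; k_min saturated at the mask size")
    } else {
      k_min <- n_mask + 1L
      warning("no cluster size controls the family-wise error at alpha = ",
              corrected_alpha, "; threshold saturated")
    }
  }
  structure(list(
    k_min = as.integer(k_min), voxel_p = voxel_p,
    corrected_alpha = corrected_alpha, null_max_sizes = max_sizes,
    n_iter = as.integer(n_iter), connectivity = as.integer(connectivity),
    fwhm_vox = fwhm3, saturated = saturated, seed = as.integer(seed)
  ), class = "cluster_threshold")
}

#' @export
print.cluster_threshold <- function(x, ...) {
  cat(sprintf(
    "<cluster_threshold> k_min = %d voxels (voxel p < %g, corrected alpha %g, %d iter, connectivity %d)%s\n",
    x$k_min, x$voxel_p, x$corrected_alpha, x$n_iter, x$connectivity,
    if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Threshold a t-map into significant and trend clusters
#'
#' Applies the one-sided cluster-forming threshold (voxelwise p from the t
#' distribution with the map's residual df) in the requested direction,
#' labels suprathreshold voxels by connected components, and classifies each
#' cluster as `significant` (size >= `k_min`) or `trend` (suprathreshold but
#' smaller than `k_min`).
#'
#' @param tmap a `stat_map` from [fit_voxelwise()] / [fit_interaction()].
#' @param threshold a `cluster_threshold` from [simulate_cluster_threshold()].
#' @param direction `"positive"` (t > cut) or `"negative"` (operates on -t).
#' @return An object of class `cluster_report`: integer `labels` map, a
#'   `clusters` data frame (cluster_id, n_voxels, peak_t signed, peak world
#'   coordinates, status), `direction`, `k_min`, `t_cut`, `affine`.
#' @export
threshold_and_cluster <- function(tmap, threshold,
                                  direction = c("positive", "negative")) {
  stopifnot(inherits(tmap, "stat_map"),
            inherits(threshold, "cluster_threshold"))
  direction <- match.arg(direction)
  if (tmap$df_resid < 1L) stop("df_resid must be >= 1", call. = FALSE)
  t_cut <- qt(1 - threshold$voxel_p, tmap$df_resid)
  vals <- if (direction == "negative") -tmap$t else tmap$t
  supra <- (vals > t_cut) & tmap$mask
  cc <- label_components(supra, threshold$connectivity)
  m <- length(cc$sizes)
  if (m == 0L) {
    clusters <- data.frame(cluster_id = integer(0), n_voxels = integer(0),
                           peak_t = numeric(0), peak_x = numeric(0),
                           peak_y = numeric(0), peak_z = numeric(0),
                           status = character(0))
  } else {
    clusters <- data.frame(cluster_id = seq_len(m), n_voxels = cc$sizes,
                           peak_t = NA_real_, peak_x = NA_real_,
                           peak_y = NA_real_, peak_z = NA_real_,
                           status = ifelse(cc$sizes >= threshold$k_min,
                                           "significant", "trend"))
    for (cid in seq_len(m)) {
      vox <- which(cc$labels == cid)
      peak <- vox[which.max(vals[vox])]
      ijk <- arrayInd(peak, dim(vals))[1L, ]
      world <- voxel_to_world(ijk, tmap$affine)
      clusters$peak_t[cid] <- tmap$t[peak] # signed t at the peak
      clusters$peak_x[cid] <- world[1L]
      clusters$peak_y[cid] <- world[2L]
      clusters$peak_z[cid] <- world[3L]
    }
  }
  structure(list(
    labels = cc$labels, clusters = clusters, direction = direction,
    k_min = threshold$k_min, t_cut = t_cut, voxel_p = threshold$voxel_p,
    affine = tmap$affine, model_label = tmap$model_label
  ), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %s direction, t > %.3f, k_min = %d: %d cluster(s), %d significant\n",
              x$direction, x$t_cut, x$k_min, nrow(x$clusters),
              sum(x$clusters$status == "significant")))
  if (nrow(x$clusters) > 0L) print(x$clusters, digits = 4)
  invisible(x)
}

#' Binary map of significant-cluster voxels
#' @param report a `cluster_report`.
#' @return 3-D logical array.
#' @export
significant_voxels <- function(report) {
  sig_ids <- report$clusters$cluster_id[report$clusters$status == "significant"]
  array(report$labels %in% sig_ids, dim(report$labels))
}

#' Dice overlap between two binary volumes
#' @param a,b 3-D logical arrays on the same grid.
#' @return `2|A&B| / (|A| + |B|)`; `NaN` when both are empty.
#' @export
dice_overlap <- function(a, b) {
  a <- a > 0; b <- b > 0
  2 * sum(a & b) / (sum(a) + sum(b))
}
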