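#' Build a design matrix aligned to a volume stack
#'
#' Assembles the regressors for the mass-univariate models: intercept, the SMD
#' w-score, optionally a centred moderator and the SMD-by-moderator product,
#' and the age/sex/education nuisance covariates that are regressed out of
#' every model. Rows with any missing regressor are removed listwise (with a
#' logged count) and the returned object records which stack volumes to keep.
#'
#' @param cohort a [cohort_table()].
#' @param smd_w named numeric vector of (reversed) SMD w-scores.
#' @param moderator optional named numeric vector (e.g. MMSE or the
#'   episodic-memory w-score); centred before any product is formed.
#' @param interaction include the `smd_w x moderator` product term?
#' @param covariates include age, sex, education?
#' @param ids participant ids defining row order (default: cohort order).
#' @return An object of class `design_matrix`: numeric matrix `X` with named
#'   columns, `ids` (rows kept), and `target` column name.
#' @export
build_design <- function(cohort, smd_w, moderator = NULL,
                         interaction = FALSE, covariates = TRUE,
                         ids = cohort$participant_id) {
  stopifnot(inherits(cohort, "cohort_table"))
  rows <- match(ids, cohort$participant_id)
  if (anyNA(rows)) stop("ids not present in cohort", call. = FALSE)
  co <- cohort[rows, , drop = FALSE]
  X <- cbind(intercept = rep(1, nrow(co)), smd_w = unname(smd_w[ids]))
  target <- "smd_w"
  if (!is.null(moderator)) {
    mod <- unname(moderator[ids])
    mod_c <- mod - mean(mod, na.rm = TRUE)
    X <- cbind(X, moderator = mod_c)
    if (interaction) {
      X <- cbind(X, `smd_w:moderator` = X[, "smd_w"] * mod_c)
      target <- "smd_w:moderator"
    }
  }
  if (covariates) {
    X <- cbind(X, age = co$age, sex_male = as.numeric(co$sex == "male"),
               education = co$education)
  }
  keep <- complete.cases(X)
  if (any(!keep)) {
    message(sprintf("design: dropped %d row(s) with missing regressors",
                    sum(!keep)))
  }
  structure(list(X = X[keep, , drop = FALSE], ids = ids[keep],
                 target = target),
            class = "design_matrix")
}

assert_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  qrX
}

#' Mass-univariate voxelwise regression
#'
#' Fits the same ordinary-least-squares model at every in-mask voxel using a
#' single QR factorization of the design (identical to voxel-by-voxel
#' regressions, independent of voxel order) and maps the t-statistic of the
#' target coefficient: `t = beta_target / SE(beta_target)` with
#' `df_resid = n - rank(design)`. Standardized residual volumes
#' (per-voxel residual divided by the voxel's residual SD) are retained for
#' smoothness estimation.
#'
#' @param stack a [volume_stack()].
#' @param design a `design_matrix` from [build_design()].
#' @param target coefficient whose t-statistic is mapped (default: the
#'   design's target column).
#' @param model_label free-text label carried into reports.
#' @return An object of class `stat_map`: 3-D `t` and `beta` maps (zero
#'   outside the mask), `df_resid`, 4-D standardized `residuals`, `mask`,
#'   `affine`, `ids`, `model_label`.
#' @export
fit_voxelwise <- function(stack, design, target = design$target,
                          model_label = target) {
  stopifnot(inherits(stack, "volume_stack"),
            inherits(design, "design_matrix"))
  sel <- match(design$ids, stack$ids)
  if (anyNA(sel)) stop("design ids missing from volume stack", call. = FALSE)
  X <- design$X
  if (!target %in% colnames(X)) {
    stop("target column '", target, "' not in design", call. = FALSE)
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 2L) {
    stop("sample too small: n = ", n, " for ", p, " regressors", call. = FALSE)
  }
  qrX <- assert_full_rank(X)

  dm <- dim(stack$data)[2:4]
  vox <- which(stack$mask)
  flat <- matrix(stack$data, dim(stack$data)[1L], prod(dm))
  Y <- flat[sel, vox, drop = FALSE]

  beta <- qr.coef(qrX, Y)
  resid <- qr.resid(qrX, Y)
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot),
                                 drop = FALSE]
  ct <- xtx_inv[match(target, colnames(X)), match(target, colnames(X))]
  se <- sqrt(sigma2 * ct)
  b_t <- beta[match(target, colnames(X)), ]
  tval <- ifelse(se > 0, b_t / se, 0)
  if (any(se == 0)) {
    warning("zero residual variance at ", sum(se == 0),
            " voxel(s); t set to 0 there")
  }

  tmap <- array(0, dm); tmap[vox] <- tval
  bmap <- array(0, dm); bmap[vox] <- b_t
  sd_vox <- sqrt(sigma2)
  std_resid <- sweep(resid, 2L, ifelse(sd_vox > 0, sd_vox, 1), "/")
  res4 <- array(0, c(n, dm))
  res_flat <- matrix(res4, n, prod(dm))
  res_flat[, vox] <- std_resid
  res4 <- array(res_flat, c(n, dm))

  structure(list(
    t = tmap, beta = bmap, df_resid = df, residuals = res4,
    mask = stack$mask, affine = stack$affine, ids = design$ids,
    target = target, model_label = model_label, n = n
  ), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s | n = %d, df = %d | t range [%.3g, %.3g]\n",
              x$model_label, x$n, x$df_resid,
              min(x$t[x$mask]), max(x$t[x$mask])))
  invisible(x)
}

#' Voxelwise SMD-by-moderator interaction model
#'
#' Fits `value ~ 1 + smd_w + moderator + smd_w:moderator + age + sex +
#' education` at every voxel, with the moderator mean-centred before the
#' product is formed, and maps the signed t of the product term. Negative-t
#' and positive-t maps are thresholded separately downstream, mirroring the
#' separate reporting of negative and positive interactions.
#'
#' @param stack a [volume_stack()].
#' @param cohort a [cohort_table()].
#' @param smd_w named (reversed) SMD w-scores.
#' @param moderator named numeric moderator (MMSE or episodic-memory w-score).
#' @param model_label label carried into reports.
#' @return A `stat_map` for the interaction coefficient.
#' @export
fit_interaction <- function(stack, cohort, smd_w, moderator,
                            model_label = "smd_w x moderator") {
  design <- build_design(cohort, smd_w, moderator = moderator,
                         interaction = TRUE, covariates = TRUE,
                         ids = intersect(cohort$participant_id, stack$ids))
  fit_voxelwise(stack, design, model_label = model_label)
}

#' Per-group voxelwise SMD regressions
#'
#' Fits the voxelwise regression of neurodegeneration on the SMD w-score with
#' age/sex/education covariates separately within each clinical group.
#'
#' @inheritParams fit_interaction
#' @param min_n skip groups with fewer usable participants than this.
#' @return named list of `stat_map`s, one per clinical group present.
#' @export
fit_per_group <- function(stack, cohort, smd_w, min_n = 8L) {
  out <- list()
  for (g in levels(droplevels(cohort$group))) {
    ids_g <- intersect(cohort$participant_id[cohort$group == g], stack$ids)
    if (length(ids_g) < min_n) {
      message("skipping group '", g, "': only ", length(ids_g),
              " participants")
      next
    }
    design <- build_design(cohort, smd_w, ids = ids_g)
    out[[g]] <- fit_voxelwise(stack, design,
                              model_label = paste0("smd_w | group ", g))
  }
  out
}

#' Split a moderator into tertile strata
#'
#' Rank-based thirds by default, with tied values assigned entirely to the
#' lower stratum; or the fixed MMSE cutpoints reported for the tertile
#' analyses (`high` > 28, `low` < 27, `mid` otherwise).
#'
#' @param x numeric vector (>= 3 distinct values in rank mode).
#' @param mode `"rank"` or `"fixed"`.
#' @param cutpoints for fixed mode: `c(low = 27, high = 28)` means
#'   low `< 27`, high `> 28`.
#' @return factor with levels low/mid/high.
#' @export
tertile_split <- function(x, mode = c("rank", "fixed"),
                          cutpoints = c(low = 27, high = 28)) {
  mode <- match.arg(mode)
  if (anyNA(x)) stop("moderator contains missing values", call. = FALSE)
  if (mode == "fixed") {
    lab <- ifelse(x < cutpoints[["low"]], "low",
                  ifelse(x > cutpoints[["high"]], "high", "mid"))
    return(factor(lab, levels = c("low", "mid", "high")))
  }
  n <- length(x)
  if (length(unique(x)) < 3L) {
    stop("need at least 3 distinct values to form tertiles", call. = FALSE)
  }
  s <- sort(x)
  v_low <- s[ceiling(n / 3)]
  v_high <- s[ceiling(2 * n / 3)]
  lab <- ifelse(x <= v_low, "low", ifelse(x <= v_high, "mid", "high"))
  f <- factor(lab, levels = c("low", "mid", "high"))
  if (any(table(f) == 0L)) {
    stop("ties too heavy to form three non-empty tertiles", call. = FALSE)
  }
  f
}

#' Per-participant mean over a cluster
#'
#' Extracts, for each participant, the mean voxel value within one labelled
#' cluster — the values used to plot cluster-wise correlations with the SMD
#' score.
#'
#' @param stack a [volume_stack()].
#' @param labels 3-D integer cluster label map.
#' @param cluster_id cluster label to extract.
#' @return named numeric vector, one mean per participant.
#' @export
extract_cluster_means <- function(stack, labels, cluster_id) {
  stopifnot(inherits(stack, "volume_stack"))
  vox <- which(labels == cluster_id)
  if (length(vox) == 0L) {
    stop("cluster id ", cluster_id, " not present in label map", call. = FALSE)
  }
  flat <- matrix(stack$data, dim(stack$data)[1L], prod(dim(stack$data)[2:4]))
  out <- rowMeans(flat[, vox, drop = FALSE])
  names(out) <- stack$ids
  out
}
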