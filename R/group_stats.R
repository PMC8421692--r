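#' One-way ANOVA with Tukey-Kramer post hoc comparisons
#'
#' Omnibus one-way ANOVA F-test plus all pairwise group comparisons using the
#' Tukey-Kramer procedure (studentized-range distribution, valid under unequal
#' group sizes), as used for between-group comparisons of continuous scores.
#'
#' @param values numeric vector of per-participant scores.
#' @param groups group labels (factor or character), same length as `values`.
#' @return An object of class `group_comparison`: `omnibus` (F, df_between,
#'   df_within, p), `pairwise` (data frame of mean differences and
#'   Tukey-adjusted p), and `group_summaries` (n, mean, SD per group).
#' @export
anova_tukey <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  ns <- tabulate(groups)
  if (any(ns < 2L)) {
    stop("every group needs at least 2 observations; smallest has ",
         min(ns), call. = FALSE)
  }
  summaries <- data.frame(
    group = levels(groups), n = ns,
    mean = as.numeric(tapply(values, groups, mean)),
    sd = as.numeric(tapply(values, groups, sd))
  )
  if (all(tapply(values, groups, var) == 0)) {
    if (var(values) == 0) {
      # all observations identical: no variance anywhere, F defined as 0
      pw <- pairwise_frame(levels(groups))
      pw$diff <- 0; pw$p_adj <- 1
      return(structure(list(
        omnibus = list(F = 0, df_between = k - 1L,
                       df_within = length(values) - k, p = 1),
        pairwise = pw, group_summaries = summaries
      ), class = "group_comparison"))
    }
    stop("zero within-group variance everywhere: ANOVA is degenerate",
         call. = FALSE)
  }
  fit <- aov(values ~ groups, data = data.frame(values = values, groups = groups))
  an <- anova(fit)
  tk <- TukeyHSD(fit)$groups
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  pw <- data.frame(
    group1 = vapply(pairs, `[`, "", 2L),
    group2 = vapply(pairs, `[`, "", 1L),
    diff = -tk[, "diff"], # report group1 - group2 in level order
    p_adj = tk[, "p adj"],
    row.names = NULL
  )
  structure(list(
    omnibus = list(F = an$`F value`[1L], df_between = an$Df[1L],
                   df_within = an$Df[2L], p = an$`Pr(>F)`[1L]),
    pairwise = pw,
    group_summaries = summaries
  ), class = "group_comparison")
}

pairwise_frame <- function(levels) {
  cmb <- utils::combn(levels, 2L)
  data.frame(group1 = cmb[1L, ], group2 = cmb[2L, ], stringsAsFactors = FALSE)
}

#' @export
print.group_comparison <- function(x, ...) {
  with(x$omnibus, cat(sprintf(
    "<group_comparison> F(%d, %d) = %.4g, p = %.4g\n",
    df_between, df_within, F, p)))
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Pearson chi-square tests on a group-by-category contingency table
#'
#' Omnibus Pearson chi-square (no continuity correction by default, matching
#' common neuropsychology reporting) plus all pairwise 2-row sub-table tests,
#' as used to compare the percentage of participants with a positive versus
#' negative delta score between clinical groups. Pairwise p-values are
#' unadjusted by default; `p_adjust = "holm"` is available.
#'
#' @param contingency matrix of non-negative integer counts (groups x
#'   categories) with row/column names.
#' @param correct apply Yates continuity correction (2x2 only)?
#' @param p_adjust multiplicity adjustment for the pairwise tests
#'   (`"none"` or any [stats::p.adjust] method).
#' @return An object of class `proportion_comparison`: `contingency`, `chi2`,
#'   `df`, `p`, and `pairwise` (one row per group pair).
#' @export
chisq_proportions <- function(contingency, correct = FALSE,
                              p_adjust = "none") {
  m <- as.matrix(contingency)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(m != round(m))) stop("counts must be integers", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("row and column sums must be > 0", call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  omni <- suppressWarnings(chisq.test(m, correct = correct))
  pw <- NULL
  if (nrow(m) > 2L) {
    cmb <- utils::combn(nrow(m), 2L)
    pw <- data.frame(
      group1 = rownames(m)[cmb[1L, ]], group2 = rownames(m)[cmb[2L, ]],
      chi2 = NA_real_, df = NA_integer_, p = NA_real_
    )
    for (j in seq_len(ncol(cmb))) {
      sub <- m[cmb[, j], , drop = FALSE]
      keep_col <- colSums(sub) > 0
      ts <- suppressWarnings(chisq.test(sub[, keep_col, drop = FALSE],
                                        correct = correct))
      pw$chi2[j] <- unname(ts$statistic)
      pw$df[j] <- unname(ts$parameter)
      pw$p[j] <- ts$p.value
    }
    if (p_adjust != "none") pw$p_adj <- stats::p.adjust(pw$p, p_adjust)
  }
  structure(list(
    contingency = m,
    chi2 = unname(omni$statistic), df = unname(omni$parameter),
    p = omni$p.value, pairwise = pw
  ), class = "proportion_comparison")
}

#' @export
print.proportion_comparison <- function(x, ...) {
  cat(sprintf("<proportion_comparison> chi2(%d) = %.4g, p = %.4g\n",
              x$df, x$chi2, x$p))
  if (!is.null(x$pairwise)) print(x$pairwise, digits = 4)
  invisible(x)
}

#' Delta-sign contingency table for a cohort
#'
#' Counts of positive/negative delta score per clinical group, ready for
#' [chisq_proportions()].
#'
#' @param awareness output of [compute_awareness()].
#' @return integer matrix groups x c(negative, positive).
#' @export
delta_sign_table <- function(awareness) {
  tab <- table(group = droplevels(awareness$group),
               sign = factor(awareness$delta_sign,
                             levels = c("negative", "positive")))
  unclass(as.matrix(tab))
}
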