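#' Fit a control-referenced normative model
#'
#' Ordinary least squares of a raw score on age, sex and education using the
#' control group only. The fitted model converts raw scores into w-scores:
#' age-, sex- and education-adjusted z-scores relative to controls. Sex is
#' coded female = 0 / male = 1 (any consistent coding yields identical
#' w-scores). The residual SD uses denominator n - 4 (n controls minus the
#' four regression coefficients), so it is the unbiased regression sigma.
#'
#' @param cohort a [cohort_table()] containing at least `min_controls`
#'   controls with complete outcome and covariates.
#' @param outcome name of the cohort column to model (e.g. `"smd_raw"`).
#' @param min_controls minimum control sample size (default 5).
#' @return An object of class `norm_model` with elements `outcome_name`,
#'   `coefficients` (intercept, age, sex_male, education), `residual_sd`,
#'   `n_reference` and `covariate_coding`.
#' @export
fit_norm_model <- function(cohort, outcome, min_controls = 5L) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!outcome %in% names(cohort)) {
    stop("unknown outcome column '", outcome, "'", call. = FALSE)
  }
  ctrl <- cohort[cohort$group == "control", , drop = FALSE]
  ctrl <- ctrl[complete.cases(ctrl[, c(outcome, "age", "sex", "education")]), ,
               drop = FALSE]
  n <- nrow(ctrl)
  if (n < min_controls) {
    stop("need at least ", min_controls, " control participants with complete ",
         "data to fit the normative model; got ", n, call. = FALSE)
  }
  X <- cbind(intercept = 1, age = ctrl$age,
             sex_male = as.numeric(ctrl$sex == "male"),
             education = ctrl$education)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    # intercept-only degenerate designs (all controls identical covariates)
    # still admit a fit on the non-aliased columns
    if (qrX$rank == 0L) stop("degenerate design: no usable columns", call. = FALSE)
  }
  y <- ctrl[[outcome]]
  fit <- lm(y ~ age + sex_male + education,
            data = data.frame(y = y, age = ctrl$age,
                              sex_male = as.numeric(ctrl$sex == "male"),
                              education = ctrl$education))
  beta <- coef(fit)
  beta[is.na(beta)] <- 0 # aliased columns contribute nothing to prediction
  names(beta) <- c("intercept", "age", "sex_male", "education")
  res <- y - (beta[["intercept"]] + beta[["age"]] * ctrl$age +
                beta[["sex_male"]] * as.numeric(ctrl$sex == "male") +
                beta[["education"]] * ctrl$education)
  p <- 4L
  if (n <= p) stop("too few controls for residual SD with denominator n - 4",
                   call. = FALSE)
  residual_sd <- sqrt(sum(res^2) / (n - p))
  if (!is.finite(residual_sd) || residual_sd <= 0) {
    stop("degenerate normative fit: residual SD is not positive ",
         "(controls have no outcome variability around the fit)",
         call. = FALSE)
  }
  structure(list(
    outcome_name = outcome,
    coefficients = beta,
    residual_sd = residual_sd,
    n_reference = n,
    covariate_coding = c(sex = "female=0, male=1")
  ), class = "norm_model")
}

#' @export
print.norm_model <- function(x, ...) {
  cat("<norm_model> outcome:", x$outcome_name,
      "| n_ref:", x$n_reference,
      "| residual SD:", signif(x$residual_sd, 5), "\n")
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' Predicted raw score under a normative model
#' @param object a `norm_model`.
#' @param cohort a [cohort_table()] (or data frame with age, sex, education).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.norm_model <- function(object, cohort, ...) {
  sx <- as.character(cohort$sex)
  if (any(!sx %in% SEX_LEVELS, na.rm = TRUE)) {
    stop("sex level outside the model's coding (expected female/male)",
         call. = FALSE)
  }
  b <- object$coefficients
  b[["intercept"]] + b[["age"]] * cohort$age +
    b[["sex_male"]] * as.numeric(sx == "male") +
    b[["education"]] * cohort$education
}

#' Compute w-scores under a fitted normative model
#'
#' `w = (observed - predicted) / residual_sd` for every participant,
#' controls and patients alike.
#'
#' @param cohort a [cohort_table()].
#' @param model a `norm_model` from [fit_norm_model()].
#' @param outcome column to transform; defaults to the model's outcome.
#' @return named numeric vector of w-scores (names = participant ids).
#' @export
compute_wscores <- function(cohort, model, outcome = model$outcome_name) {
  stopifnot(inherits(model, "norm_model"))
  obs <- cohort[[outcome]]
  w <- (obs - predict(model, cohort)) / model$residual_sd
  names(w) <- cohort$participant_id
  w
}

#' Delta memory-awareness score
#'
#' `delta = objmem_w - smd_w_reversed`. A positive delta means the participant
#' rates their memory worse than their objective performance warrants
#' (overestimation of difficulties); a negative delta means they underestimate
#' their difficulties, the direction suggestive of anosognosia. Zero is
#' classified as positive (non-negative); ties are a measure-zero event under
#' continuous scores.
#'
#' @param smd_w_reversed reversed SMD w-score (higher = better self-rated
#'   memory).
#' @param objmem_w objective-memory w-score (higher = better performance).
#' @return list with numeric `delta` and character `sign`
#'   (`"positive"`/`"negative"`), vectorized over inputs.
#' @export
delta_score <- function(smd_w_reversed, objmem_w) {
  if (any(!is.finite(smd_w_reversed)) || any(!is.finite(objmem_w))) {
    stop("delta_score requires finite inputs", call. = FALSE)
  }
  delta <- objmem_w - smd_w_reversed
  list(delta = delta, sign = ifelse(delta >= 0, "positive", "negative"))
}

#' Full w-score / delta table for a cohort
#'
#' Fits control-referenced normative models for the subjective (SMD) and
#' objective memory scores, computes w-scores for every participant, reverses
#' the SMD w-score by negation (exactly equivalent to reversing the raw scale
#' as `max - raw` under the linear normative model, and requiring no
#' questionnaire maximum) so that higher values mean better self-rated memory,
#' and forms the delta score.
#'
#' @param cohort a [cohort_table()].
#' @param min_controls passed to [fit_norm_model()].
#' @return data frame with columns `participant_id`, `group`, `smd_w`
#'   (reversed), `objmem_w`, `delta`, `delta_sign`, plus attributes
#'   `norm_models` (the two fitted models).
#' @export
compute_awareness <- function(cohort, min_controls = 5L) {
  cohort_cc <- drop_incomplete(
    cohort, c("smd_raw", "objmem_raw", "age", "sex", "education"),
    context = "awareness scoring")
  m_smd <- fit_norm_model(cohort_cc, "smd_raw", min_controls)
  m_obj <- fit_norm_model(cohort_cc, "objmem_raw", min_controls)
  smd_w_rev <- -compute_wscores(cohort_cc, m_smd) # reversal: negate the w-score
  obj_w <- compute_wscores(cohort_cc, m_obj)
  d <- delta_score(smd_w_rev, obj_w)
  out <- data.frame(
    participant_id = cohort_cc$participant_id,
    group = cohort_cc$group,
    smd_w = as.numeric(smd_w_rev),
    objmem_w = as.numeric(obj_w),
    delta = as.numeric(d$delta),
    delta_sign = d$sign,
    stringsAsFactors = FALSE
  )
  attr(out, "norm_models") <- list(smd = m_smd, objmem = m_obj)
  out
}
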