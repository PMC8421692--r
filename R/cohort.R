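#' @importFrom stats anova coef lm median pchisq pf pt ptukey qnorm qt
#'   quantile rbinom rnorm sd setNames var complete.cases cor cor.test
#'   predict aov TukeyHSD chisq.test
#' @importFrom utils read.csv write.csv
NULL

GROUP_LEVELS <- c("control", "scd", "mci", "dementia")
SEX_LEVELS <- c("female", "male")

REQUIRED_COHORT_COLUMNS <- c(
  "participant_id", "group", "age", "sex", "education",
  "mmse", "smd_raw", "objmem_raw"
)

#' Construct and validate a cohort table
#'
#' A cohort table holds one row per participant: demographics, clinical group
#' (control, SCD, MCI or dementia), MMSE global cognition, the raw subjective
#' memory decline (SMD) questionnaire score (higher = more complaints), the raw
#' objective episodic-memory score (higher = better performance) and,
#' optionally, amyloid status.
#'
#' @param df data frame with columns `participant_id`, `group`, `age`, `sex`,
#'   `education`, `mmse`, `smd_raw`, `objmem_raw` and optionally
#'   `amyloid_positive`. `group` and `sex` are parsed case-insensitively.
#' @return A validated `data.frame` of class `cohort_table` with `group` and
#'   `sex` as factors on the canonical levels.
#' @export
cohort_table <- function(df) {
  if (!is.data.frame(df)) stop("`df` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(REQUIRED_COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$participant_id <- as.character(df$participant_id)

  grp <- tolower(trimws(as.character(df$group)))
  bad <- !is.na(grp) & !(grp %in% GROUP_LEVELS)
  if (any(bad)) {
    stop("unknown clinical group value(s): ",
         paste(unique(grp[bad]), collapse = ", "),
         " (expected control/scd/mci/dementia)", call. = FALSE)
  }
  df$group <- factor(grp, levels = GROUP_LEVELS)

  sx <- tolower(trimws(as.character(df$sex)))
  sx[sx %in% c("f")] <- "female"
  sx[sx %in% c("m")] <- "male"
  bad <- !is.na(sx) & !(sx %in% SEX_LEVELS)
  if (any(bad)) {
    stop("unknown sex value(s): ", paste(unique(sx[bad]), collapse = ", "),
         call. = FALSE)
  }
  df$sex <- factor(sx, levels = SEX_LEVELS)

  for (col in c("age", "education", "mmse", "smd_raw", "objmem_raw")) {
    v <- df[[col]]
    if (is.character(v) || is.factor(v)) {
      vt <- suppressWarnings(as.numeric(as.character(v)))
      bad_rows <- which(!is.na(v) & v != "" & is.na(vt))
      if (length(bad_rows) > 0L) {
        stop("non-numeric value in column '", col, "' at row ",
             paste(bad_rows, collapse = ", "), call. = FALSE)
      }
      v <- vt
    }
    df[[col]] <- as.numeric(v)
  }
  if ("amyloid_positive" %in% names(df)) {
    v <- df$amyloid_positive
    if (!is.logical(v)) {
      vc <- tolower(trimws(as.character(v)))
      out <- rep(NA, length(vc))
      out[vc %in% c("true", "t", "1", "yes")] <- TRUE
      out[vc %in% c("false", "f", "0", "no")] <- FALSE
      bad_rows <- which(!is.na(vc) & vc != "" & is.na(out))
      if (length(bad_rows) > 0L) {
        stop("non-boolean amyloid_positive value at row ",
             paste(bad_rows, collapse = ", "), call. = FALSE)
      }
      df$amyloid_positive <- out
    }
  }

  dup <- duplicated(df$participant_id)
  if (any(dup)) {
    stop("duplicate participant_id value(s): ",
         paste(unique(df$participant_id[dup]), collapse = ", "), call. = FALSE)
  }
  bad_mmse <- which(!is.na(df$mmse) & (df$mmse < 0 | df$mmse > 30))
  if (length(bad_mmse) > 0L) {
    stop("mmse outside [0, 30] at row ", paste(bad_mmse, collapse = ", "),
         " (value ", paste(df$mmse[bad_mmse], collapse = ", "), ")",
         call. = FALSE)
  }
  bad_age <- which(!is.na(df$age) & df$age <= 0)
  if (length(bad_age) > 0L) {
    stop("age must be > 0; offending row ", paste(bad_age, collapse = ", "),
         call. = FALSE)
  }
  bad_edu <- which(!is.na(df$education) & df$education < 0)
  if (length(bad_edu) > 0L) {
    stop("education must be >= 0; offending row ",
         paste(bad_edu, collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a cohort table from CSV
#'
#' Expects a comma-separated, UTF-8, '.'-decimal file whose header contains
#' `participant_id, group, age, sex, education, mmse, smd_raw, objmem_raw`
#' (plus optionally `amyloid_positive`). The optional amyloid column may be
#' absent; analyses that need it fail late with a clear message.
#'
#' @param path path to the CSV file.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                 colClasses = "character")
  cohort_table(df)
}

#' Write a cohort table to CSV
#'
#' Round-trips through [read_cohort()] without loss.
#'
#' @param cohort a [cohort_table()].
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  write.csv(as.data.frame(cohort), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x), " participants\n", sep = "")
  print(table(group = x$group))
  invisible(x)
}

# Drop rows with missing values in `cols`, with a logged count (the analyses
# use listwise deletion per model).
drop_incomplete <- function(cohort, cols, context = "analysis") {
  keep <- complete.cases(cohort[, cols, drop = FALSE])
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(sprintf("%s: dropped %d participant(s) with missing %s",
                    context, n_drop, paste(cols, collapse = "/")))
  }
  cohort[keep, , drop = FALSE]
}
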