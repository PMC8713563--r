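#' Score the nine-item trauma questionnaire
#'
#' Each item is coded 1 = yes, 0 = no. The raw exposure count is the
#' unweighted sum of the nine items; for regression the count is capped at
#' 3 (subjects with three or more events form one group).
#'
#' @param items Numeric/integer vector of nine values in \{0, 1\}, or a
#'   matrix with nine columns (one row per subject). A row containing any
#'   `NA` is treated as missing as a block and returns `NA` counts; missing
#'   records are flagged for exclusion by [apply_qc()], never silently
#'   zeroed.
#' @return For a vector, a list with `te_count_raw` and `te_coded`; for a
#'   matrix, a data.frame with those two columns.
#' @export
score_te <- function(items) {
  if (is.matrix(items) || is.data.frame(items)) {
    items <- as.matrix(items)
    if (ncol(items) != 9L) stop("expected nine items per subject")
    bad <- items[!is.na(items)]
    if (any(bad != 0 & bad != 1)) stop("items must be 0 or 1")
    miss <- rowSums(is.na(items)) > 0L
    raw <- ifelse(miss, NA_integer_, as.integer(rowSums(items)))
    return(data.frame(te_count_raw = raw,
                      te_coded = pmin(raw, 3L)))
  }
  if (length(items) != 9L) stop("expected nine items")
  if (anyNA(items)) return(list(te_count_raw = NA_integer_, te_coded = NA_integer_))
  if (any(items != 0 & items != 1)) stop("items must be 0 or 1")
  raw <- as.integer(sum(items))
  list(te_count_raw = raw, te_coded = min(raw, 3L))
}

#' Apply participant-level inclusion filters
#'
#' Applies the exclusion gates in a fixed order -- mean motion per TR,
#' censored-frame fraction, (optional) co-registration failure, brain
#' injury, missing trauma items, missing maternal education -- and records
#' the first reason triggered for each excluded subject. Motion and censor
#' thresholds use strict inequality: a subject at exactly 0.3 mm mean
#' motion or exactly a 30% censor fraction is included.
#'
#' @param subjects Data.frame with columns `subject_id`,
#'   `mean_motion_per_tr`, `censor_fraction`, `brain_injury`,
#'   `item1`..`item9` (or precomputed `te_count_raw`), `maternal_education`,
#'   and optionally logical `coreg_fail`.
#' @param motion_mm Mean-motion exclusion threshold (mm, strict `>`).
#' @param censor_max Censor-fraction exclusion threshold (strict `>`).
#' @return List with `included` and `excluded` data.frames (both carrying
#'   `te_count_raw`, `te_coded`, `qc_pass`, `exclusion_reason`) and a named
#'   integer vector `counts` of exclusions per reason.
#' @export
apply_qc <- function(subjects, motion_mm = 0.3, censor_max = 0.3) {
  stopifnot(is.data.frame(subjects))
  need <- c("subject_id", "mean_motion_per_tr", "censor_fraction",
            "brain_injury", "maternal_education")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- subjects
  if (!all(c("te_count_raw", "te_coded") %in% names(df))) {
    sc <- score_te(df[paste0("item", 1:9)])
    df$te_count_raw <- sc$te_count_raw
    df$te_coded <- sc$te_coded
  }
  reason <- rep(NA_character_, nrow(df))
  gate <- function(cond, tag) {
    hit <- is.na(reason) & cond
    reason[hit] <<- tag
  }
  gate(df$mean_motion_per_tr > motion_mm, "motion")
  gate(df$censor_fraction > censor_max, "censor_fraction")
  if ("coreg_fail" %in% names(df)) gate(isTRUE_vec(df$coreg_fail), "coreg_fail")
  gate(isTRUE_vec(df$brain_injury), "brain_injury")
  gate(is.na(df$te_count_raw), "missing_trauma")
  gate(is.na(df$maternal_education), "missing_maternal_education")

  df$qc_pass <- is.na(reason)
  df$exclusion_reason <- reason
  lev <- c("motion", "censor_fraction", "coreg_fail", "brain_injury",
           "missing_trauma", "missing_maternal_education")
  counts <- table(factor(reason, levels = lev))
  included <- df[df$qc_pass, , drop = FALSE]
  if (nrow(included) == 0L) warning("no subjects pass quality control")
  list(included = included,
       excluded = df[!df$qc_pass, , drop = FALSE],
       counts = counts)
}

# vector-safe isTRUE
isTRUE_vec <- function(x) !is.na(x) & x

#' Demographics by exposure level
#'
#' Summarises the included sample per capped exposure count: n, percentage
#' female, mean/SD age, mean/SD maternal education. SDs that are undefined
#' (single subject) are reported as `NA`.
#'
#' @param included Data.frame of included subjects (must carry `te_coded`,
#'   `sex`, `age`, `maternal_education`).
#' @return A data.frame with one row per exposure level.
#' @export
demographics_table <- function(included) {
  stopifnot(is.data.frame(included), nrow(included) > 0L)
  sp <- split(included, included$te_coded)
  rows <- lapply(names(sp), function(k) {
    g <- sp[[k]]
    data.frame(
      te_coded = as.integer(k),
      n = nrow(g),
      pct_female = 100 * mean(g$sex == "female"),
      age_mean = mean(g$age),
      age_sd = if (nrow(g) > 1L) stats::sd(g$age) else NA_real_,
      maternal_education_mean = mean(g$maternal_education),
      maternal_education_sd = if (nrow(g) > 1L) stats::sd(g$maternal_education)
                              else NA_real_
    )
  })
  do.call(rbind, rows)
}
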