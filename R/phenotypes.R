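# Coefficient vectors over protocol days defining each derived variable.
# AUC is the trapezoidal rule over exposure index 1..5 (unit spacing):
# (D3 + D11)/2 + D5 + D7 + D9. The simple-sum rule is available via
# `auc_rule = "sum"`.
.phenotype_coefs <- function(auc_rule = c("trapezoid", "sum")) {
  auc_rule <- match.arg(auc_rule)
  auc <- if (auc_rule == "trapezoid") {
    c(`3` = 0.5, `5` = 1, `7` = 1, `9` = 1, `11` = 0.5)
  } else {
    c(`3` = 1, `5` = 1, `7` = 1, `9` = 1, `11` = 1)
  }
  list(
    day1 = c(`1` = 1),
    day2 = c(`2` = 1),
    habituation = c(`2` = 1, `1` = -1),
    initial_response = c(`3` = 1, `2` = -1),
    initial_sensitization = c(`5` = 1, `3` = -1),
    auc = auc,
    expression = c(`19` = 1, `11` = -1),
    conditioned_activation = c(`12` = 1, `2` = -1)
  )
}

#' Day sets underlying each derived sensitization variable
#'
#' The set of protocol test days that enter each derived variable's
#' computation. This provenance drives the autocorrelation mask used in the
#' strain-mean correlation analysis: a derived variable is never correlated
#' against a day (or another variable) it shares a day with.
#'
#' @param auc_rule `"trapezoid"` (default) or `"sum"`; both use the same days.
#' @return Named list of integer day vectors, one per derived variable.
#' @examples
#' phenotype_day_sets()$auc  # 3 5 7 9 11
#' @export
phenotype_day_sets <- function(auc_rule = "trapezoid") {
  lapply(.phenotype_coefs(auc_rule), function(cf) sort(as.integer(names(cf))))
}

#' Derive the sensitization variables from one mouse's distance series
#'
#' Given the per-day distances of a single mouse, computes the eight derived
#' variables: day-1 and day-2 locomotion, habituation (day 2 - day 1),
#' initial locomotor response to cocaine (day 3 - day 2), initial
#' sensitization (day 5 - day 3), sensitization AUC across the five
#' consecutive cocaine exposures (days 3,5,7,9,11), sensitization expression
#' after the drug-free week (day 19 - day 11) and conditioned activation
#' (day 12 - day 2). A variable is `NA` iff any of its constituent days is
#' missing; the reasons are recorded in the `"missing_reason"` attribute.
#'
#' @param series named numeric vector: names are test days, values distances
#'   (cm). Days absent from the protocol are ignored.
#' @param auc_rule `"trapezoid"` (default) or `"sum"`.
#' @return Named numeric vector of the eight derived variables, with
#'   attribute `missing_reason` (named character vector for `NA` fields).
#' @examples
#' s <- c(`1` = 100, `2` = 150, `3` = 400, `5` = 500, `7` = 600, `9` = 700,
#'        `11` = 800, `12` = 200, `19` = 820)
#' derive_variables(s)
#' @export
derive_variables <- function(series, auc_rule = "trapezoid") {
  if (any(series < 0, na.rm = TRUE)) {
    stop("invariant error: negative distance in series")
  }
  coefs <- .phenotype_coefs(auc_rule)
  out <- vapply(coefs, function(cf) {
    d <- series[names(cf)]
    if (anyNA(d) || length(d) < length(cf)) NA_real_ else sum(cf * d)
  }, numeric(1))
  reasons <- character()
  for (v in names(coefs)) {
    if (is.na(out[[v]])) {
      need <- names(coefs[[v]])
      miss <- need[!need %in% names(series) | is.na(series[need])]
      reasons[[v]] <- paste0("missing day(s) ", paste(miss, collapse = ","))
    }
  }
  attr(out, "missing_reason") <- reasons
  out
}

#' Derive per-mouse phenotypes for a whole cohort
#'
#' Applies [derive_variables()] to every mouse and joins the result to the
#' mouse-level covariates (strain, sex, site, treatment group, day-1 body
#' weight). Per-day distances are carried along as `day_1`, `day_2`, ...
#' columns because single-day locomotion enters the heritability survey and
#' the correlation matrix alongside the derived variables.
#'
#' @param table a `cohort_table` (see [read_cohort()], [as_cohort_table()]).
#' @param auc_rule `"trapezoid"` (default) or `"sum"`.
#' @return A tibble with one row per mouse, ordered by `mouse_id`: covariates,
#'   `day_<d>` distance columns, then the eight derived variables.
#' @export
derive_cohort <- function(table, auc_rule = "trapezoid") {
  sched <- protocol_schedule()
  mice <- sort(unique(table$mouse_id))
  idx <- match(mice, table$mouse_id)
  # wide per-day distance matrix, one row per mouse
  wide <- matrix(NA_real_, nrow = length(mice), ncol = length(sched$test_days),
                 dimnames = list(mice, as.character(sched$test_days)))
  wide[cbind(match(table$mouse_id, mice),
             match(table$day, sched$test_days))] <- table$distance
  derived <- t(apply(wide, 1L, derive_variables, auc_rule = auc_rule))
  out <- tibble::tibble(
    mouse_id = mice,
    strain = table$strain[idx],
    sex = table$sex[idx],
    site = table$site[idx],
    treatment_group = table$treatment_group[idx],
    body_weight = table$body_weight[idx]
  )
  day_cols <- tibble::as_tibble(as.data.frame(wide))
  names(day_cols) <- paste0("day_", sched$test_days)
  out <- tibble::as_tibble(cbind(out, day_cols, tibble::as_tibble(as.data.frame(derived))))
  attr(out, "auc_rule") <- auc_rule
  attr(out, "day_sets") <- phenotype_day_sets(auc_rule)
  out
}
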