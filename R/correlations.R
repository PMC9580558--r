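# Default Table-3-style variable set for the strain-mean correlation matrix:
# single days interleaved with the derived variables, body weight last.
.correlation_variables <- function() {
  c("day_1", "day_2", "habituation", "day_3", "initial_response",
    "day_5", "initial_sensitization", "day_7", "day_9", "day_11",
    "auc", "conditioned_activation", "day_12", "expression", "day_19",
    "body_weight")
}

# day-set provenance for correlation variables; body_weight is day-1 weight
# but is exempt from the day-overlap mask (empty set)
.correlation_day_sets <- function(variables = .correlation_variables()) {
  sets <- lapply(variables, function(v) {
    if (v == "body_weight") return(integer())
    sort(as.integer(names(.variable_coefs(v))))
  })
  names(sets) <- variables
  sets
}

#' Autocorrelation mask for the strain-mean correlation matrix
#'
#' A correlation between two variables is suppressed ("masked") when their
#' underlying day sets intersect — a derived difference score or AUC shares
#' raw data with the individual days it is computed from, so their
#' correlation is an autocorrelation, not a biological relationship. Two
#' distinct single-day variables never share a day and are never masked;
#' body weight carries an empty day set and is exempt.
#'
#' @param day_sets named list of integer day vectors, one per variable (see
#'   [phenotype_day_sets()]); or a character vector of variable names from
#'   which the day sets are looked up.
#' @return Symmetric logical matrix; `TRUE` marks a masked pair. The
#'   diagonal is `FALSE` (a variable is not paired with itself).
#' @examples
#' m <- autocorrelation_mask(c("auc", "day_7", "day_1"))
#' m["auc", "day_7"]  # TRUE: day 7 is inside the AUC window
#' @export
autocorrelation_mask <- function(day_sets) {
  if (is.character(day_sets)) day_sets <- .correlation_day_sets(day_sets)
  k <- length(day_sets)
  nm <- names(day_sets)
  m <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && length(intersect(day_sets[[i]], day_sets[[j]])) > 0L) {
        m[i, j] <- TRUE
      }
    }
  }
  m
}

#' Strain-by-variable matrix of arithmetic strain means
#'
#' @param phenotypes per-mouse phenotype table from [derive_cohort()].
#' @param arm treatment arm to retain (default `"cocaine"`); `NULL` keeps
#'   all mice.
#' @param variables variable columns to average; defaults to the Table-3
#'   style set (single days, derived variables, body weight).
#' @return Numeric matrix, strains in rows (sorted), variables in columns;
#'   `NA` where a strain has no non-missing value.
#' @export
strain_means <- function(phenotypes, arm = "cocaine",
                         variables = .correlation_variables()) {
  dat <- if (is.null(arm)) phenotypes else
    phenotypes[phenotypes$treatment_group == arm, ]
  stopifnot(all(variables %in% names(dat)))
  strains <- sort(unique(dat$strain))
  out <- matrix(NA_real_, length(strains), length(variables),
                dimnames = list(strains, variables))
  for (v in variables) {
    mv <- tapply(dat[[v]], dat$strain, mean, na.rm = TRUE)
    mv[is.nan(mv)] <- NA
    out[names(mv), v] <- mv
  }
  out
}

#' Masked Pearson correlations among strain means
#'
#' Pairwise Pearson product-moment correlations across strains
#' (pairwise-complete), skipping masked pairs, with two-sided p-values from
#' the t transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} and a Bonferroni flag at
#' corrected 0.05. The Bonferroni denominator is the number of unmasked,
#' reportable pairs (the visible cells of the matrix), recorded in the
#' `"n_tests"` attribute.
#'
#' @param means strain x variable matrix from [strain_means()].
#' @param mask logical matrix from [autocorrelation_mask()] (defaults to the
#'   mask implied by the column names); `NULL` disables masking.
#' @param min_n minimum number of complete strain pairs to report a
#'   correlation (default 3).
#' @return A tibble with one row per unordered variable pair: `var1`,
#'   `var2`, `masked`, `r`, `n`, `p_unadjusted`, `p_bonferroni`,
#'   `bonferroni_significant`, `note`. Attribute `n_tests` holds the
#'   Bonferroni denominator.
#' @export
pearson_matrix <- function(means, mask = autocorrelation_mask(colnames(means)),
                           min_n = 3L) {
  vars <- colnames(means)
  k <- length(vars)
  if (is.null(mask)) mask <- matrix(FALSE, k, k, dimnames = list(vars, vars))
  pairs <- utils::combn(k, 2L)
  np <- ncol(pairs)
  res <- vector("list", np)
  for (idx in seq_len(np)) {
    i <- pairs[1L, idx]; j <- pairs[2L, idx]
    if (mask[vars[i], vars[j]]) {
      res[[idx]] <- tibble::tibble(var1 = vars[i], var2 = vars[j],
                                   masked = TRUE, r = NA_real_, n = NA_integer_,
                                   p_unadjusted = NA_real_,
                                   note = "masked: shared day(s)")
      next
    }
    ok <- stats::complete.cases(means[, c(i, j)])
    n <- sum(ok)
    if (n < min_n) {
      res[[idx]] <- tibble::tibble(var1 = vars[i], var2 = vars[j],
                                   masked = FALSE, r = NA_real_, n = n,
                                   p_unadjusted = NA_real_,
                                   note = "fewer than min_n complete strains")
      next
    }
    x <- means[ok, i]; y <- means[ok, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      res[[idx]] <- tibble::tibble(var1 = vars[i], var2 = vars[j],
                                   masked = FALSE, r = NA_real_, n = n,
                                   p_unadjusted = NA_real_,
                                   note = "zero variance")
      next
    }
    r <- stats::cor(x, y)
    p <- if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
    }
    res[[idx]] <- tibble::tibble(var1 = vars[i], var2 = vars[j],
                                 masked = FALSE, r = r, n = as.integer(n),
                                 p_unadjusted = p, note = NA_character_)
  }
  out <- do.call(rbind, res)
  n_tests <- sum(!out$masked & !is.na(out$r))
  out$p_bonferroni <- pmin(1, out$p_unadjusted * n_tests)
  out$bonferroni_significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < 0.05
  attr(out, "n_tests") <- n_tests
  out
}

#' Cross-site replicability correlations of strain means
#'
#' Pearson correlation, per variable, between the strain means measured at
#' two test sites across the strains present at both. The degrees of
#' freedom reported are `n - 2` (the convention `r(df)` used when quoting
#' such correlations).
#'
#' @param means_a,means_b strain x variable matrices from [strain_means()]
#'   for the two sites (row names are strains).
#' @param variables variables to correlate; defaults to the columns shared
#'   by both matrices.
#' @param min_n minimum number of shared strains (default 3); variables
#'   with fewer are skipped with a warning.
#' @return A tibble: `variable`, `r`, `n`, `df`, `p`.
#' @export
cross_site_correlation <- function(means_a, means_b,
                                   variables = intersect(colnames(means_a),
                                                         colnames(means_b)),
                                   min_n = 3L) {
  shared <- intersect(rownames(means_a), rownames(means_b))
  rows <- vector("list", length(variables))
  for (i in seq_along(variables)) {
    v <- variables[i]
    xa <- means_a[shared, v]
    xb <- means_b[shared, v]
    ok <- !is.na(xa) & !is.na(xb)
    n <- sum(ok)
    if (n < min_n) {
      warning("variable ", v, ": only ", n, " shared strain(s); skipped")
      next
    }
    r <- stats::cor(xa[ok], xb[ok])
    p <- if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
    }
    rows[[i]] <- tibble::tibble(variable = v, r = r, n = as.integer(n),
                                df = as.integer(n - 2L), p = p)
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
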