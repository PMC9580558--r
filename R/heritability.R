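#' One-way strain ANOVA mean squares
#'
#' Decomposes a per-mouse phenotype into between-strain and within-strain
#' mean squares: `ms_strain` = sum over strains of `n_i (ybar_i - ybar)^2 /
#' (a - 1)` and `ms_resid` = pooled within-strain sum of squares divided by
#' `N - a`. Also returns the two sample-size summaries the heritability
#' machinery needs: `n_bar`, the arithmetic mean of per-strain counts (the
#' "mean number of mice per strain" that enters the point estimate), and
#' `n0 = (N - sum(n_i^2)/N)/(a - 1)`, the unbalanced-design effective group
#' size used when extracting variance components for the bootstrap.
#'
#' @param values numeric per-mouse phenotype vector; `NA`s are dropped.
#' @param strain strain label per mouse.
#' @return A `mean_squares` list: `ms_strain`, `ms_resid`, `df_strain`,
#'   `df_resid`, `n_bar`, `n0`, `grand_mean`, `counts` (named per-strain).
#' @examples
#' strain_anova(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
#' @export
strain_anova <- function(values, strain) {
  ok <- !is.na(values) & !is.na(strain)
  values <- values[ok]
  strain <- as.character(strain)[ok]
  counts <- table(strain)
  a <- length(counts)
  if (a < 2L) stop("strain ANOVA requires at least 2 strains with data")
  if (any(counts < 2L)) {
    warning(sum(counts < 2L), " strain(s) with a single observation ",
            "contribute no residual degrees of freedom")
  }
  n_tot <- length(values)
  gm <- mean(values)
  grp_mean <- tapply(values, strain, mean)
  ss_strain <- sum(as.numeric(counts) * (grp_mean - gm)^2)
  ss_resid <- sum((values - grp_mean[strain])^2)
  df_strain <- a - 1L
  df_resid <- n_tot - a
  if (df_resid <= 0L) stop("no residual degrees of freedom")
  structure(list(
    ms_strain = ss_strain / df_strain,
    ms_resid = ss_resid / df_resid,
    df_strain = df_strain,
    df_resid = df_resid,
    n_bar = mean(as.numeric(counts)),
    n0 = (n_tot - sum(as.numeric(counts)^2) / n_tot) / df_strain,
    grand_mean = gm,
    counts = counts
  ), class = "mean_squares")
}

#' Broad-sense heritability point estimate from strain mean squares
#'
#' \deqn{H^2 = \frac{MS_{strain}}{MS_{strain} + (\bar n - 1)\, MS_{resid}}}
#'
#' where \eqn{\bar n} is the mean number of mice per strain. `H^2` lies
#' strictly in (0, 1) whenever both mean squares are positive and
#' \eqn{\bar n > 1}.
#'
#' @param ms a `mean_squares` object from [strain_anova()].
#' @return The point estimate, or `NA` (with a `"reason"` attribute) when
#'   both mean squares are zero.
#' @export
h2_point <- function(ms) {
  stopifnot(inherits(ms, "mean_squares"))
  denom <- ms$ms_strain + (ms$n_bar - 1) * ms$ms_resid
  if (denom == 0) {
    return(structure(NA_real_, reason = "both mean squares are zero"))
  }
  ms$ms_strain / denom
}

# vectorized one-way ANOVA + H2 across B simulated replicate columns.
# `y` is an N x B matrix, rows grouped by `strain`.
.h2_columns <- function(y, strain, n_bar) {
  n_tot <- nrow(y)
  a <- length(unique(strain))
  counts <- as.numeric(table(strain)[unique(strain)])
  gmean <- colMeans(y)
  gsum <- rowsum(y, strain, reorder = FALSE)
  gmeans <- gsum / counts
  ss_strain <- colSums(counts * sweep(gmeans, 2L, gmean)^2)
  ss_tot <- colSums(sweep(y, 2L, gmean)^2)
  ms_strain <- ss_strain / (a - 1L)
  ms_resid <- (ss_tot - ss_strain) / (n_tot - a)
  ms_strain / (ms_strain + (n_bar - 1) * ms_resid)
}

#' Model-based bootstrap standard error for a heritability estimate
#'
#' Extracts variance components from the observed mean squares —
#' \eqn{\hat\sigma^2_s = \max(0, (MS_{strain} - MS_{resid})/n_0)},
#' \eqn{\hat\sigma^2_e = MS_{resid}} — then simulates `n_boot` new cohorts
#' from the fitted one-way random-effects model
#' \eqn{y^*_{ij} = \bar y + s^*_i + e^*_{ij}} preserving the observed
#' per-strain counts, recomputes `H^2` on each, and reports the standard
#' deviation of the replicate estimates as the standard error.
#'
#' @param ms a `mean_squares` object from [strain_anova()].
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed RNG seed; the result is deterministic given `seed`.
#' @return A `heritability_estimate` list: `h2`, `se`, `n_boot`, `seed`,
#'   `sigma2_strain`, `sigma2_resid`, `boot_mean`.
#' @export
h2_bootstrap <- function(ms, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(ms, "mean_squares"))
  if (n_boot < 2L) stop("n_boot must be at least 2 for a standard error")
  sigma2_s <- max(0, (ms$ms_strain - ms$ms_resid) / ms$n0)
  sigma2_e <- ms$ms_resid
  counts <- as.numeric(ms$counts)
  a <- length(counts)
  n_tot <- sum(counts)
  strain <- rep(seq_len(a), times = counts)
  h2_rep <- .with_seed(seed, {
    s_star <- matrix(stats::rnorm(a * n_boot, 0, sqrt(sigma2_s)), a, n_boot)
    e_star <- matrix(stats::rnorm(n_tot * n_boot, 0, sqrt(sigma2_e)),
                     n_tot, n_boot)
    y_star <- ms$grand_mean + s_star[strain, , drop = FALSE] + e_star
    .h2_columns(y_star, strain, ms$n_bar)
  })
  structure(list(
    h2 = h2_point(ms),
    se = stats::sd(h2_rep),
    n_boot = as.integer(n_boot),
    seed = seed,
    sigma2_strain = sigma2_s,
    sigma2_resid = sigma2_e,
    boot_mean = mean(h2_rep)
  ), class = "heritability_estimate")
}

#' Heritability survey over derived variables and single days
#'
#' Computes the broad-sense heritability point estimate and bootstrap
#' standard error for each requested variable, in the cocaine arm only
#' (genetic differences in drug response are only visible in drug-exposed
#' animals). Missing values are dropped per variable.
#'
#' @param phenotypes a per-mouse phenotype table from [derive_cohort()].
#' @param arm treatment arm to survey (default `"cocaine"`).
#' @param variables variables to survey; defaults to the eight derived
#'   variables followed by per-day locomotion.
#' @param n_boot bootstrap replicates per variable.
#' @param seed RNG seed (each variable uses an offset of it).
#' @return A tibble with one row per variable: `variable`, `h2`, `se`,
#'   `n_strains`, `n_mice`, `n_boot`.
#' @export
h2_survey <- function(phenotypes, arm = "cocaine",
                      variables = c(names(.phenotype_coefs()),
                                    paste0("day_", protocol_schedule()$test_days)),
                      n_boot = 1000L, seed = 1L) {
  dat <- phenotypes[phenotypes$treatment_group == arm, ]
  rows <- vector("list", length(variables))
  for (i in seq_along(variables)) {
    v <- variables[i]
    if (!v %in% names(dat) || all(is.na(dat[[v]]))) {
      warning("variable ", v, " has no data; skipped")
      next
    }
    ms <- strain_anova(dat[[v]], dat$strain)
    est <- h2_bootstrap(ms, n_boot = n_boot, seed = seed + i)
    rows[[i]] <- tibble::tibble(
      variable = v, h2 = as.numeric(est$h2), se = est$se,
      n_strains = length(ms$counts), n_mice = sum(ms$counts),
      n_boot = est$n_boot
    )
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
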