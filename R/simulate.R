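#' Configuration for the synthetic sensitization cohort generator
#'
#' Defines the generative model for a synthetic strain-survey cohort:
#' per-day distance for mouse *m* of strain *s* on test day *d* is
#'
#' \deqn{y = \mu + strain_s + mouse_m + day_d + treatment\ terms +
#'       sex\cdot 1[F] + site\cdot 1[JAX] + \varepsilon,\qquad
#'       \varepsilon \sim N(0, \sigma^2_e),}
#'
#' with `strain_s ~ N(0, var_strain)`, `mouse_m ~ N(0, var_mouse)`. Cocaine
#' days in the drug arm add an acute shift plus a cumulative sensitization
#' ramp over exposure index (with a strain-specific slope drawn from
#' `N(0, var_strain_slope)`); day 12 in the drug arm adds
#' `conditioned_effect`; day 19 adds the full ramp plus `expression_effect`.
#' Distances are floored at zero after noise.
#'
#' The defaults approximate the shape of the strain survey the package
#' targets: 59 strains (51 CC + 8 founders), two treatment arms, eight mice
#' per strain per arm, nine test days, locomotor distances of a few thousand
#' cm per 60-min session.
#'
#' @param n_strains number of strains.
#' @param mice_per_strain_per_arm scalar (balanced) or length-`n_strains`
#'   vector of mice per strain in each treatment arm.
#' @param var_strain variance of the strain baseline effect (cm^2).
#' @param var_strain_slope variance of the strain-specific per-exposure
#'   sensitization slope.
#' @param var_mouse per-mouse random intercept variance (cm^2).
#' @param var_resid day-level residual variance (cm^2); must be > 0.
#' @param grand_mean grand mean distance (cm).
#' @param day_effects length-9 vector of day shifts aligned with the protocol
#'   test days.
#' @param cocaine_acute_effect mean shift on the first cocaine exposure (cm).
#' @param ramp length-5 vector of per-exposure sensitization increments
#'   (cumulative over exposures 1..5).
#' @param expression_effect additional day-19 shift in the drug arm (cm).
#' @param conditioned_effect day-12 shift in the drug arm (cm).
#' @param sex_effect additive female-minus-male shift (cm).
#' @param site_effect additive JAX-minus-UNC shift (cm).
#' @param sex_ratio probability a mouse is female.
#' @param site_assignment `"JAX"`, `"UNC"`, or `"split"` (mice alternate
#'   between the two sites within each strain/arm).
#' @param seed default RNG seed used by [simulate_cohort()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_strains = 59L,
                       mice_per_strain_per_arm = 8L,
                       var_strain = 1e6,
                       var_strain_slope = 4e4,
                       var_mouse = 2.5e5,
                       var_resid = 1e6,
                       grand_mean = 4000,
                       day_effects = rep(0, 9L),
                       cocaine_acute_effect = 3000,
                       ramp = c(0, 600, 500, 400, 300),
                       expression_effect = 0,
                       conditioned_effect = 500,
                       sex_effect = 300,
                       site_effect = 500,
                       sex_ratio = 0.5,
                       site_assignment = "JAX",
                       seed = 1L) {
  cfg <- list(
    n_strains = as.integer(n_strains),
    mice_per_strain_per_arm = as.integer(mice_per_strain_per_arm),
    var_strain = var_strain, var_strain_slope = var_strain_slope,
    var_mouse = var_mouse, var_resid = var_resid,
    grand_mean = grand_mean, day_effects = as.numeric(day_effects),
    cocaine_acute_effect = cocaine_acute_effect, ramp = as.numeric(ramp),
    expression_effect = expression_effect,
    conditioned_effect = conditioned_effect,
    sex_effect = sex_effect, site_effect = site_effect,
    sex_ratio = sex_ratio, site_assignment = site_assignment,
    seed = as.integer(seed)
  )
  if (any(c(cfg$var_strain, cfg$var_strain_slope, cfg$var_mouse) < 0)) {
    stop("config error: variances must be non-negative")
  }
  if (cfg$var_resid < 0) stop("config error: var_resid must be non-negative")
  if (length(cfg$ramp) != 5L) stop("config error: ramp must have length 5")
  if (length(cfg$day_effects) != 9L) {
    stop("config error: day_effects must have length 9")
  }
  if (!site_assignment %in% c("JAX", "UNC", "split")) {
    stop("config error: unknown site_assignment")
  }
  if (!length(cfg$mice_per_strain_per_arm) %in% c(1L, cfg$n_strains)) {
    stop("config error: mice_per_strain_per_arm must be scalar or per-strain")
  }
  structure(cfg, class = "sim_config")
}

#' Read or write a simulation config as JSON
#'
#' @param path JSON file path.
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   invisibly returns `path`.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# run expr with an isolated RNG stream seeded by `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a synthetic sensitization cohort
#'
#' Generates a long-format cohort table under the generative model described
#' in [sim_config()], together with the realized latent parameters. The
#' output is deterministic given `config` and `seed`.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A list with
#'   * `cohort` — a `cohort_table` (one row per mouse per test day),
#'   * `truth` — list with `strain_effects`, `strain_slopes`,
#'     `mouse_effects` (tibbles), `h2_expected` (named vector of plug-in
#'     heritability expectations per variable, balanced designs only),
#'     `n_truncated` (rows floored at zero) and the `config`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_strains = 4, mice_per_strain_per_arm = 2))
#' head(sim$cohort)
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  sched <- protocol_schedule()
  a <- config$n_strains
  n_arm <- rep(config$mice_per_strain_per_arm, length.out = a)
  strains <- sprintf("S%03d", seq_len(a))

  .with_seed(seed, {
    strain_eff <- stats::rnorm(a, 0, sqrt(config$var_strain))
    strain_slope <- stats::rnorm(a, 0, sqrt(config$var_strain_slope))

    # mouse-level frame: both arms, per-strain counts
    m_strain <- rep(rep(strains, times = n_arm), 2L)
    m_arm <- rep(c("cocaine", "saline"), each = sum(n_arm))
    n_mice <- length(m_strain)
    m_id <- sprintf("M%05d", seq_len(n_mice))
    m_eff <- stats::rnorm(n_mice, 0, sqrt(config$var_mouse))
    m_sex <- ifelse(stats::runif(n_mice) < config$sex_ratio, "F", "M")
    m_site <- switch(config$site_assignment,
      JAX = rep("JAX", n_mice),
      UNC = rep("UNC", n_mice),
      split = {
        # alternate within strain x arm so both sites see every strain
        s <- character(n_mice)
        for (g in split(seq_len(n_mice), paste(m_strain, m_arm))) {
          s[g] <- rep(c("JAX", "UNC"), length.out = length(g))
        }
        s
      })
    m_weight <- pmax(10, stats::rnorm(n_mice, ifelse(m_sex == "M", 25, 21), 2))

    days <- sched$test_days
    n_days <- length(days)
    row_mouse <- rep(seq_len(n_mice), each = n_days)
    row_day <- rep(days, times = n_mice)
    row_dayidx <- rep(seq_len(n_days), times = n_mice)
    si <- match(m_strain, strains)[row_mouse]

    mu <- config$grand_mean + config$day_effects[row_dayidx] +
      strain_eff[si] + m_eff[row_mouse] +
      ifelse(m_sex[row_mouse] == "F", config$sex_effect, 0) +
      ifelse(m_site[row_mouse] == "JAX", config$site_effect, 0)

    is_coc_arm <- m_arm[row_mouse] == "cocaine"
    expo <- .exposure_index(row_day, sched)  # 1..6 on drug-group cocaine days
    cum_ramp <- cumsum(config$ramp)
    drug_day <- is_coc_arm & !is.na(expo)
    k <- expo[drug_day]
    treat <- numeric(length(row_day))
    treat[drug_day] <- config$cocaine_acute_effect +
      cum_ramp[pmin(k, 5L)] +
      strain_slope[si[drug_day]] * (pmin(k, 5L) - 1L) +
      ifelse(k == 6L, config$expression_effect, 0)
    treat[is_coc_arm & row_day == 12L] <- config$conditioned_effect

    y <- mu + treat + stats::rnorm(length(row_day), 0, sqrt(config$var_resid))
    n_trunc <- sum(y < 0)
    if (n_trunc > 0L) {
      message(n_trunc, " simulated distance(s) truncated at 0")
    }
    y <- pmax(y, 0)

    cohort <- as_cohort_table(tibble::tibble(
      mouse_id = m_id[row_mouse],
      strain = m_strain[row_mouse],
      sex = m_sex[row_mouse],
      site = m_site[row_mouse],
      treatment_group = m_arm[row_mouse],
      day = row_day,
      distance = y,
      body_weight = m_weight[row_mouse]
    ), source = "simulate_cohort")

    h2_exp <- NULL
    if (length(unique(n_arm)) == 1L) {
      vars <- c(names(.phenotype_coefs()), paste0("day_", days))
      h2_exp <- vapply(vars, function(v) {
        tryCatch(plugin_h2_expectation(config, v),
                 error = function(e) NA_real_)
      }, numeric(1))
    }
    list(
      cohort = cohort,
      truth = list(
        strain_effects = tibble::tibble(strain = strains, effect = strain_eff,
                                        slope = strain_slope),
        mouse_effects = tibble::tibble(mouse_id = m_id, strain = m_strain,
                                       treatment_group = m_arm, sex = m_sex,
                                       site = m_site, effect = m_eff),
        h2_expected = h2_exp,
        n_truncated = n_trunc,
        config = config,
        seed = seed
      )
    )
  })
}

# day-coefficient vector for any surveyed variable: a derived phenotype name
# or "day_<d>" for single-day locomotion
.variable_coefs <- function(variable, auc_rule = "trapezoid") {
  coefs <- .phenotype_coefs(auc_rule)
  if (variable %in% names(coefs)) return(coefs[[variable]])
  if (grepl("^day_[0-9]+$", variable)) {
    d <- sub("^day_", "", variable)
    cf <- c(1)
    names(cf) <- d
    return(cf)
  }
  stop("unknown variable: ", variable)
}

#' Plug-in heritability expectation under a simulation config
#'
#' For a balanced config, returns the analytic plug-in value of the
#' mean-squares heritability estimator for a derived variable in the cocaine
#' arm: \eqn{(\sigma^2_B + \sigma^2_W/n)/(\sigma^2_B + \sigma^2_W)}, where
#' the between-strain variance \eqn{\sigma^2_B} and within-strain variance
#' \eqn{\sigma^2_W} are those the config induces for that variable (a linear
#' combination of per-day distances) and `n` is mice per strain. Used as the
#' oracle in estimator-recovery tests.
#'
#' @param config a balanced [sim_config()].
#' @param variable a derived variable name (e.g. `"auc"`) or `"day_<d>"`.
#' @return The plug-in expectation, in (0, 1].
#' @export
plugin_h2_expectation <- function(config, variable) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$mice_per_strain_per_arm) != 1L) {
    stop("unsupported design: plug-in expectation requires a balanced config")
  }
  n <- config$mice_per_strain_per_arm
  cf <- .variable_coefs(variable)
  days <- as.integer(names(cf))
  expo <- .exposure_index(days)
  slope_load <- ifelse(is.na(expo), 0, pmin(expo, 5L) - 1L)
  c_sum <- sum(cf)
  sigma_b <- c_sum^2 * config$var_strain +
    sum(cf * slope_load)^2 * config$var_strain_slope
  sigma_w <- c_sum^2 * config$var_mouse + sum(cf^2) * config$var_resid
  if (sigma_b + sigma_w <= 0) stop("degenerate config: zero total variance")
  (sigma_b + sigma_w / n) / (sigma_b + sigma_w)
}
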