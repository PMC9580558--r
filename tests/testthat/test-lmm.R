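library(lmerTest)

# small mixed cohort reused across tests
lmm_cohort <- function(seed = 1, n_strains = 4, n_arm = 3) {
  sim <- quiet_sim(sim_config(n_strains = n_strains,
                              mice_per_strain_per_arm = n_arm, seed = seed))
  coh <- sim$cohort
  coh$rdist <- residualize_sex(coh$distance, coh$sex)
  coh
}

test_that("sex residualization removes exactly the sex-group means", {
  # values fully explained by sex
  expect_equal(residualize_sex(c(10, 10, 20, 20), c("F", "F", "M", "M")),
               rep(0, 4))
  # balanced, no sex effect: residuals are the centered values
  v <- c(1, 3, 3, 1)
  expect_equal(residualize_sex(v, c("F", "M", "F", "M")), v - 2)
  # hand-computed OLS on a toy vector
  expect_equal(residualize_sex(c(1, 2, 3, 4), c("F", "F", "M", "M")),
               c(-0.5, 0.5, -0.5, 0.5))
  # residuals sum to zero within each sex, and the map is idempotent
  set.seed(4)
  v2 <- stats::rnorm(20)
  sx <- rep(c("F", "M"), 10)
  r <- residualize_sex(v2, sx)
  expect_equal(sum(r[sx == "F"]), 0)
  expect_equal(sum(r[sx == "M"]), 0)
  expect_equal(residualize_sex(r, sx), r)
  # single sex: mean-centering with a warning
  expect_warning(r1 <- residualize_sex(c(1, 2, 3), c("F", "F", "F")), "single")
  expect_equal(r1, c(-1, 0, 1))
})

test_that("balanced one-way REML equals the method-of-moments closed form", {
  set.seed(42)
  a <- 6
  nper <- 5
  d <- data.frame(strain = rep(LETTERS[1:a], each = nper),
                  mouse_id = seq_len(a * nper))
  d$y <- stats::rnorm(a * nper, rep(stats::rnorm(a, 0, 2), each = nper), 1)
  fit <- fit_lmm(d, "y", fixed = character(), group = "strain")
  ms <- strain_anova(d$y, d$strain)
  expect_equal(fit$var_resid, ms$ms_resid, tolerance = 1e-6)
  expect_equal(fit$var_group, (ms$ms_strain - ms$ms_resid) / nper,
               tolerance = 1e-6)
})

test_that("REML estimates agree with lmer on a factorial cohort", {
  coh <- lmm_cohort(seed = 2)
  fit <- fit_lmm(coh, "rdist")
  coh$dayf <- factor(coh$day)
  m <- lmer(rdist ~ dayf * treatment_group * strain + (1 | mouse_id),
            data = coh, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))$vcov
  expect_equal(fit$var_group, vc[1], tolerance = 1e-5)
  expect_equal(fit$var_resid, vc[2], tolerance = 1e-5)
  # cell means match the lmer fixed-effect predictions
  pred <- unique(data.frame(day = as.character(coh$day),
                            treatment_group = coh$treatment_group,
                            strain = coh$strain))
  pred$dayf <- factor(pred$day, levels = levels(coh$dayf))
  mm <- stats::model.matrix(~ dayf * treatment_group * strain, pred)
  cellhat <- drop(mm %*% lme4::fixef(m))
  key <- paste(pred$day, pred$treatment_group, pred$strain, sep = ":")
  expect_equal(unname(fit$beta[key]), unname(cellhat), tolerance = 1e-6)
})

test_that("returned variance ratio beats a log-spaced grid", {
  coh <- lmm_cohort(seed = 3)
  fit <- fit_lmm(coh, "rdist")
  obj <- function(lam) ccsens:::.reml_objective(lam, fit$X, fit$y, fit$gidx,
                                                fit$gsizes)
  at_opt <- obj(fit$lambda)
  grid_vals <- vapply(10^seq(-6, 6, length.out = 64), obj, numeric(1))
  expect_true(all(grid_vals >= at_opt - 1e-6))
})

test_that("degenerate zero-variance data yield exact cell means", {
  d <- expand.grid(day = c(1, 2, 3), treatment_group = c("cocaine", "saline"),
                   strain = c("A", "B"), rep = 1:2,
                   stringsAsFactors = FALSE)
  d$mouse_id <- paste(d$treatment_group, d$strain, d$rep)
  d$y <- 10 * as.integer(factor(paste(d$day, d$treatment_group, d$strain)))
  expect_warning(fit <- fit_lmm(d, "y"), "degenerate")
  expect_true(fit$degenerate)
  expect_identical(fit$var_group, 0)
  expect_lt(fit$var_resid, 1e-12)
  truth <- tapply(d$y, paste(d$day, d$treatment_group, d$strain, sep = ":"),
                  mean)
  expect_equal(unname(fit$beta[names(truth)]), as.numeric(truth))
})

test_that("one observation per group reduces to OLS at the boundary", {
  set.seed(9)
  d <- data.frame(g = rep(c("A", "B", "C"), each = 4))
  d$mouse_id <- seq_len(nrow(d))
  d$y <- stats::rnorm(nrow(d), as.integer(factor(d$g)))
  fit <- fit_lmm(d, "y", fixed = "g", group = "mouse_id")
  expect_true(fit$boundary)
  expect_identical(fit$var_group, 0)
  ols <- stats::lm(y ~ 0 + g, data = d)
  expect_equal(unname(fit$beta), unname(stats::coef(ols)), tolerance = 1e-8)
  expect_equal(unname(fit$cov_beta), unname(stats::vcov(ols)),
               tolerance = 1e-8)
  expect_equal(fit$var_resid, summary(ols)$sigma^2, tolerance = 1e-8)
})

test_that("ANOVA F and Satterthwaite df match lmerTest", {
  coh <- lmm_cohort(seed = 6)
  fit <- fit_lmm(coh, "rdist")
  at <- anova_table(fit)
  coh$dayf <- factor(coh$day)
  m <- lmer(rdist ~ dayf * treatment_group * strain + (1 | mouse_id),
            data = coh)
  ref <- stats::anova(m, type = 3)
  key <- c(day = "dayf", treatment_group = "treatment_group",
           strain = "strain", `day:treatment_group` = "dayf:treatment_group",
           `day:strain` = "dayf:strain",
           `treatment_group:strain` = "treatment_group:strain",
           `day:treatment_group:strain` = "dayf:treatment_group:strain")
  ref <- ref[key[at$term], ]
  expect_equal(at$F, ref[["F value"]], tolerance = 1e-4)
  expect_equal(at$df1, ref$NumDF)
  expect_equal(at$df2, ref$DenDF, tolerance = 1e-2)
  expect_equal(at$p, ref[["Pr(>F)"]], tolerance = 1e-3)
})

test_that("boundary fits fall back to the classical fixed-effects df", {
  # one obs per mouse: the mouse variance is unidentifiable, the fit sits at
  # the boundary, and every term's denominator df is the residual df
  set.seed(10)
  d <- expand.grid(day = 1:3, treatment_group = c("cocaine", "saline"),
                   rep = 1:4, stringsAsFactors = FALSE)
  d$mouse_id <- seq_len(nrow(d))
  d$y <- stats::rnorm(nrow(d))
  fit <- fit_lmm(d, "y", fixed = c("day", "treatment_group"))
  expect_true(fit$boundary)
  at <- anova_table(fit)
  expect_true(all(at$df2 == nrow(d) - 6))
})

test_that("single-factor balanced ANOVA equals the classical one-way F", {
  # 3 groups x 4 observations, one per mouse
  set.seed(12)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 4))
  d$mouse_id <- seq_len(nrow(d))
  d$y <- stats::rnorm(nrow(d), c(1, 2, 4)[as.integer(factor(d$g))])
  fit <- fit_lmm(d, "y", fixed = "g")
  at <- anova_table(fit)
  ref <- summary(stats::aov(y ~ g, data = d))[[1]]
  expect_equal(at$F, ref[["F value"]][1], tolerance = 1e-8)
  expect_equal(at$df1, ref$Df[1])
  expect_equal(at$df2, ref$Df[2])
  expect_equal(at$p, ref[["Pr(>F)"]][1], tolerance = 1e-8)
})

test_that("tukey_hsd matches the t-test at k = 2 and TukeyHSD in general", {
  # k = 2 reduction
  means <- c(a = 1, b = 3)
  se <- 0.8
  df <- 14
  out <- tukey_hsd(means, se, df)
  tstat <- 2 / se
  expect_equal(out$p_tukey, 2 * stats::pt(tstat, df, lower.tail = FALSE),
               tolerance = 1e-8)
  # identical means: p = 1
  out0 <- tukey_hsd(c(2, 2, 2), 0.5, 10)
  expect_true(all(abs(out0$p_tukey - 1) < 1e-8))
  # monotone decreasing p in |difference| at fixed se, k, df
  ps <- vapply(seq(0.2, 3, by = 0.2), function(d) {
    tukey_hsd(c(0, d), 1, 12, k_family = 4)$p_tukey
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  # against stats::TukeyHSD on a balanced one-way design
  set.seed(15)
  d <- data.frame(g = factor(rep(c("a", "b", "c", "d"), each = 5)))
  d$y <- stats::rnorm(20, as.integer(d$g))
  av <- stats::aov(y ~ g, data = d)
  ref <- stats::TukeyHSD(av)$g
  mse <- summary(av)[[1]][["Mean Sq"]][2]
  mine <- tukey_hsd(tapply(d$y, d$g, mean), sqrt(2 * mse / 5), df = 16)
  expect_equal(mine$p_tukey, unname(ref[, "p adj"]), tolerance = 1e-6)
  expect_equal(mine$estimate, unname(ref[, "diff"]), tolerance = 1e-10)
  expect_error(tukey_hsd(c(1, 2), 1, df = 0), "df")
})

test_that("responder classification finds a large treatment effect", {
  cfg <- sim_config(n_strains = 3, mice_per_strain_per_arm = 8,
                    var_strain = 0, var_strain_slope = 0, var_mouse = 0,
                    var_resid = 1e4, grand_mean = 3000,
                    cocaine_acute_effect = 500, ramp = rep(0, 5),
                    conditioned_effect = 0, sex_effect = 0, site_effect = 0,
                    seed = 21)
  coh <- quiet_sim(cfg)$cohort
  coh$rdist <- residualize_sex(coh$distance, coh$sex)
  fit <- fit_lmm(coh, "rdist")
  rsp <- classify_responders(fit)
  expect_true(all(rsp$responder))
  expect_true(all(rsp$p_tukey >= rsp$p_unadjusted - 1e-12))
  # estimate = mean treatment effect over days: 6 of 9 days carry ~500
  expect_equal(rsp$estimate, rep(500 * 6 / 9, 3), tolerance = 0.15)
})

test_that("a strain present in one arm only is inestimable", {
  coh <- lmm_cohort(seed = 8)
  drop_strain <- unique(coh$strain)[1]
  coh2 <- coh[!(coh$strain == drop_strain &
                  coh$treatment_group == "saline"), ]
  fit <- fit_lmm(coh2, "rdist")
  expect_gt(length(fit$empty_cells), 0)
  rsp <- classify_responders(fit)
  expect_false(rsp$estimable[rsp$strain == drop_strain])
  expect_false(rsp$responder[rsp$strain == drop_strain])
  expect_true(all(rsp$estimable[rsp$strain != drop_strain]))
  # Type III machinery refuses the incomplete factorial explicitly
  expect_error(anova_table(fit), "empty cell")
})

test_that("fixed-effects Type III ANOVA matches a hand-computed 2x2", {
  # balanced 2x2, one observation per cell pair: Type III == classical SS
  d <- data.frame(
    strain = rep(c("A", "B"), each = 4),
    sex = rep(c("F", "F", "M", "M"), 2),
    y = c(10, 12, 20, 22, 30, 32, 44, 46)
  )
  out <- anova_fixed(d, "y", factors = c("strain", "sex"))
  ref <- summary(stats::aov(y ~ strain * sex, data = d))[[1]]
  rownames(ref) <- trimws(rownames(ref))
  for (tm in c("strain", "sex", "strain:sex")) {
    expect_equal(out$F[out$term == tm], ref[tm, "F value"], tolerance = 1e-10)
  }
  expect_true(all(out$df2 == 4))
})

test_that("single-level factors are dropped from the fixed ANOVA", {
  d <- data.frame(strain = rep(c("A", "B"), each = 4),
                  sex = rep(c("F", "M"), 4),
                  site = "JAX",
                  y = stats::rnorm(8))
  expect_warning(out <- anova_fixed(d, "y"), "single-level.*site")
  expect_false(any(grepl("site", out$term)))
})

test_that("null site effects give uniform fixed-ANOVA p-values", {
  set.seed(33)
  ps <- vapply(1:120, function(i) {
    d <- expand.grid(strain = c("A", "B", "C"), sex = c("F", "M"),
                     site = c("JAX", "UNC"), rep = 1:3,
                     stringsAsFactors = FALSE)
    d$y <- stats::rnorm(nrow(d), as.integer(factor(d$strain)))
    out <- anova_fixed(d, "y")
    out$p[out$term == "site"]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
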