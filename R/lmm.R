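#' Regress sex out of a response vector
#'
#' Ordinary least-squares residuals of the response on an intercept plus a
#' sex indicator; equivalently, each observation minus its sex-group mean.
#' Residuals sum to zero overall and within each sex, and the operation is
#' idempotent. Downstream mixed-model analyses of locomotor distance take
#' these residuals as input so that sex differences do not masquerade as
#' strain or treatment effects.
#'
#' @param values numeric response vector (`NA`s propagate).
#' @param sex factor/character vector of `"F"`/`"M"` (any two labels work).
#' @return Numeric vector of residuals, same length as `values`.
#' @examples
#' residualize_sex(c(1, 2, 3, 4), c("F", "F", "M", "M"))
#' @export
residualize_sex <- function(values, sex) {
  stopifnot(length(values) == length(sex))
  sex <- as.character(sex)
  ok <- !is.na(values) & !is.na(sex)
  out <- rep(NA_real_, length(values))
  if (length(unique(sex[ok])) < 2L) {
    warning("single sex level present; residuals are mean-centered values")
    out[ok] <- values[ok] - mean(values[ok])
    return(out)
  }
  grp <- tapply(values[ok], sex[ok], mean)
  out[ok] <- values[ok] - grp[sex[ok]]
  out
}

# --- profiled REML machinery for a single random intercept -----------------

# per-group half-whitening: for ratio lambda = sigma2_group / sigma2_resid,
# (I + lambda * J_n)^(-1/2) x = x - (1 - 1/sqrt(1 + lambda n)) * xbar
.whiten <- function(M, gidx, gsizes, lambda) {
  c_g <- 1 - 1 / sqrt(1 + lambda * gsizes)
  gm <- rowsum(M, gidx, reorder = TRUE) / gsizes
  M - c_g[gidx] * gm[gidx, , drop = FALSE]
}

# minus twice the restricted log-likelihood, profiled over beta and sigma2_e,
# as a function of the variance ratio lambda (up to an additive constant)
.reml_objective <- function(lambda, X, y, gidx, gsizes) {
  n <- length(y)
  p <- ncol(X)
  Xw <- .whiten(X, gidx, gsizes, lambda)
  yw <- .whiten(cbind(y), gidx, gsizes, lambda)
  qr_x <- qr(Xw)
  rss <- sum(qr.resid(qr_x, yw)^2)
  logdet_w <- sum(log1p(lambda * gsizes))
  logdet_xwx <- 2 * sum(log(abs(diag(qr.R(qr_x)))))
  (n - p) * log(rss) + logdet_w + logdet_xwx
}

# full -2 restricted log-likelihood at theta = (sigma2_group, sigma2_resid),
# used for the numeric Hessian behind Satterthwaite df
.reml_m2ll_theta <- function(theta, X, y, gidx, gsizes) {
  s2g <- theta[1]
  s2e <- theta[2]
  lambda <- s2g / s2e
  n <- length(y)
  p <- ncol(X)
  Xw <- .whiten(X, gidx, gsizes, lambda)
  yw <- .whiten(cbind(y), gidx, gsizes, lambda)
  qr_x <- qr(Xw)
  rss <- sum(qr.resid(qr_x, yw)^2)
  sum(log1p(lambda * gsizes)) + (n - p) * log(s2e) + rss / s2e +
    2 * sum(log(abs(diag(qr.R(qr_x)))))
}

# covariance of the cell means at theta
.cov_beta_theta <- function(theta, X, gidx, gsizes) {
  lambda <- theta[1] / theta[2]
  Xw <- .whiten(X, gidx, gsizes, lambda)
  theta[2] * chol2inv(chol(crossprod(Xw)))
}

#' Fit a random-intercept linear mixed model by profiled REML
#'
#' Fits `response ~ 0 + cell + (1 | group)` where `cell` is the full
#' factorial of the named fixed factors (cell-means parameterization, so the
#' fixed-effect estimates are generalized-least-squares cell means) and the
#' random intercept is per mouse. The restricted likelihood is profiled down
#' to the single variance ratio `sigma2_group / sigma2_resid`, optimized by
#' golden-section/Brent search on the log ratio; given the ratio, the fixed
#' effects and residual variance have closed forms. A ratio whose objective
#' is not better than the ratio-zero boundary is reported as an exact zero
#' with `boundary = TRUE`.
#'
#' @param data data frame in long format.
#' @param response name of the response column (typically sex-residualized
#'   distance).
#' @param fixed character vector of fixed-factor column names; the design is
#'   their full factorial. Empty cells are dropped from the design (each
#'   observed cell retains its own mean) and recorded in `empty_cells`.
#' @param group name of the random-intercept grouping column (the mouse).
#' @param tol convergence tolerance on the log variance ratio.
#' @return An `lmm_fit` list: `beta` (named cell means), `cov_beta`,
#'   `var_group`, `var_resid`, `lambda`, `reml_m2ll`, `boundary`,
#'   `vcov_theta` (covariance of the two variance components), `levels`,
#'   `cells`, `empty_cells`, `df_resid`, plus the internals needed for
#'   Satterthwaite degrees of freedom.
#' @seealso [anova_table()], [classify_responders()]
#' @export
fit_lmm <- function(data, response,
                    fixed = c("day", "treatment_group", "strain"),
                    group = "mouse_id", tol = 1e-8) {
  stopifnot(all(c(response, fixed, group) %in% names(data)))
  keep <- stats::complete.cases(data[c(response, fixed, group)])
  data <- data[keep, , drop = FALSE]
  y <- as.numeric(data[[response]])
  n <- length(y)
  if (length(fixed) == 0L) {
    # intercept-only fixed design (e.g. a pure variance-components fit)
    levs <- list()
    empty_cells <- character()
    X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
    cell_levels <- "(Intercept)"
  } else {
    facs <- lapply(data[fixed], function(f) factor(f))
    levs <- lapply(facs, levels)
    # cell id with the FIRST factor varying fastest (expand.grid order), so
    # Type III contrasts can be built by Kronecker products
    all_cells <- do.call(expand.grid, c(levs, KEEP.OUT.ATTRS = FALSE,
                                        stringsAsFactors = FALSE))
    cell_names <- do.call(paste, c(all_cells, sep = ":"))
    obs_cell <- do.call(paste, c(lapply(facs, as.character), sep = ":"))
    cell_f <- factor(obs_cell, levels = cell_names)
    present <- cell_names %in% levels(droplevels(cell_f))
    empty_cells <- cell_names[!present]
    cell_f <- droplevels(cell_f)
    X <- stats::model.matrix(~ 0 + cell_f)
    colnames(X) <- levels(cell_f)
    cell_levels <- levels(cell_f)
  }
  p <- ncol(X)
  if (n <= p) stop("fewer observations than design cells")
  gf <- factor(data[[group]])
  if (nlevels(gf) < 2L) stop("need at least 2 grouping units")
  gidx <- as.integer(gf)
  gsizes <- as.numeric(tabulate(gidx))

  # degenerate data: cell means explain everything, residual variance -> 0
  qr0 <- qr(X)
  rss0 <- sum(qr.resid(qr0, y)^2)
  degenerate <- rss0 <= max(1e-14 * sum((y - mean(y))^2), 1e-300)
  if (degenerate) {
    lambda <- 0
    boundary <- TRUE
    opt <- list(objective = -Inf)
  } else {
    obj <- function(loglam) .reml_objective(exp(loglam), X, y, gidx, gsizes)
    opt <- stats::optimize(obj, interval = log(c(1e-8, 1e8)), tol = tol)
    lambda <- exp(opt$minimum)
    f_zero <- .reml_objective(0, X, y, gidx, gsizes)
    boundary <- f_zero <= opt$objective + 1e-10
    if (boundary) lambda <- 0
  }

  Xw <- .whiten(X, gidx, gsizes, lambda)
  yw <- .whiten(cbind(y), gidx, gsizes, lambda)
  qr_x <- qr(Xw)
  beta <- drop(qr.coef(qr_x, yw))
  names(beta) <- colnames(X)
  rss <- sum(qr.resid(qr_x, yw)^2)
  s2e <- rss / (n - p)
  s2g <- lambda * s2e
  cov_beta <- s2e * chol2inv(chol(crossprod(Xw)))
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  m2ll <- if (degenerate) -Inf else
    .reml_m2ll_theta(c(s2g, s2e), X, y, gidx, gsizes)
  if (degenerate) warning("zero residual variance; fit flagged degenerate")

  # observed-information covariance of theta = (var_group, var_resid) by a
  # central-difference Hessian of -2 logLik_R; at the boundary only the
  # residual variance is free
  vcov_theta <- matrix(0, 2L, 2L,
                       dimnames = list(c("var_group", "var_resid"),
                                       c("var_group", "var_resid")))
  hess_ok <- TRUE
  if (boundary) {
    vcov_theta[2L, 2L] <- 2 * s2e^2 / (n - p)
  } else {
    theta <- c(s2g, s2e)
    h <- pmax(abs(theta) * 1e-4, 1e-10)
    H <- matrix(0, 2L, 2L)
    f0 <- m2ll
    fn <- function(th) .reml_m2ll_theta(pmax(th, c(0, 1e-12)), X, y, gidx, gsizes)
    for (i in 1:2) {
      ei <- c(0, 0); ei[i] <- h[i]
      H[i, i] <- (fn(theta + ei) - 2 * f0 + fn(theta - ei)) / h[i]^2
    }
    e1 <- c(h[1], 0); e2 <- c(0, h[2])
    H[1, 2] <- H[2, 1] <-
      (fn(theta + e1 + e2) - fn(theta + e1 - e2) -
         fn(theta - e1 + e2) + fn(theta - e1 - e2)) / (4 * h[1] * h[2])
    vt <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (is.null(vt) || any(!is.finite(vt)) || any(diag(vt) < 0)) {
      hess_ok <- FALSE
    } else {
      vcov_theta <- vt
      dimnames(vcov_theta) <- dimnames(vcov_theta)
    }
  }

  structure(list(
    beta = beta, cov_beta = cov_beta,
    var_group = s2g, var_resid = s2e, lambda = lambda,
    reml_m2ll = m2ll, boundary = boundary, hess_ok = hess_ok,
    vcov_theta = vcov_theta,
    levels = levs, fixed = fixed, response = response,
    cells = cell_levels, empty_cells = empty_cells, degenerate = degenerate,
    n = n, p = p, df_resid = n - p,
    X = X, y = y, gidx = gidx, gsizes = gsizes
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept LMM (profiled REML)\n")
  cat("  ", x$n, "obs,", x$p, "design cells,", length(x$gsizes), "groups\n")
  cat("  var(group) =", format(x$var_group),
      if (x$boundary) "(boundary)" else "", "\n")
  cat("  var(resid) =", format(x$var_resid), "\n")
  invisible(x)
}

# central-difference gradient matrices of C(theta) = cov(beta) w.r.t. the
# two variance components; computed once per fit and reused for every
# Satterthwaite contrast
.satter_prep <- function(fit) {
  if (fit$boundary || !fit$hess_ok) return(NULL)
  theta <- c(fit$var_group, fit$var_resid)
  dC <- vector("list", 2L)
  for (i in 1:2) {
    h <- max(abs(theta[i]) * 1e-5, 1e-12)
    tp <- theta; tp[i] <- theta[i] + h
    tm <- theta; tm[i] <- max(theta[i] - h, 0)
    Cp <- .cov_beta_theta(tp, fit$X, fit$gidx, fit$gsizes)
    Cm <- .cov_beta_theta(tm, fit$X, fit$gidx, fit$gsizes)
    dC[[i]] <- (Cp - Cm) / (tp[i] - tm[i])
  }
  dC
}

# Satterthwaite denominator df for a single contrast c'beta:
# df = 2 f^2 / (g' V_theta g), f = c' C(theta) c, g its numeric gradient
.satterthwaite_df <- function(fit, cvec, prep = .satter_prep(fit)) {
  if (is.null(prep)) return(fit$df_resid)
  f0 <- drop(t(cvec) %*% fit$cov_beta %*% cvec)
  g <- vapply(prep, function(dC) drop(t(cvec) %*% dC %*% cvec), numeric(1))
  den <- drop(t(g) %*% fit$vcov_theta %*% g)
  if (den <= 0) return(fit$df_resid)
  df <- 2 * f0^2 / den
  min(df, fit$df_resid)
}

# Type III contrast matrix (rows = hypothesis contrasts over cells) for a
# term, built from Kronecker products over the factor list; factor 1 varies
# fastest in the cell ordering
.type3_contrast <- function(fit, term_factors) {
  if (length(fit$empty_cells) > 0L) {
    stop("Type III contrasts require a complete factorial; empty cell(s): ",
         paste(utils::head(fit$empty_cells, 3L), collapse = ", "))
  }
  mats <- lapply(seq_along(fit$fixed), function(i) {
    k <- length(fit$levels[[i]])
    if (fit$fixed[i] %in% term_factors) {
      t(stats::contr.sum(k))        # (k-1) x k difference contrasts
    } else {
      matrix(1 / k, nrow = 1L, ncol = k)  # average over this factor
    }
  })
  L <- Reduce(function(a, b) kronecker(b, a), mats)
  colnames(L) <- fit$cells
  L
}

#' Type III ANOVA table with Satterthwaite denominator df
#'
#' Wald F tests of each fixed-effect term (all main effects and
#' interactions of the factorial design) against Type III hypotheses built
#' on the cell means, with denominator degrees of freedom by the
#' Satterthwaite method: each term's contrast matrix is eigen-decomposed,
#' per-contrast df come from the delta method on the REML
#' variance-component covariance, and the 1-df values are pooled. When the
#' variance-parameter Hessian is ill-conditioned (or the group variance sits
#' at the zero boundary) the residual df are used instead, with a warning in
#' the former case.
#'
#' @param fit an [fit_lmm()] object over a complete factorial design.
#' @return A tibble: `term`, `F`, `df1`, `df2`, `p`.
#' @export
anova_table <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$hess_ok) {
    warning("variance-parameter Hessian ill-conditioned; ",
            "falling back to residual df")
  }
  prep <- .satter_prep(fit)
  k <- length(fit$fixed)
  terms <- unlist(lapply(seq_len(k), function(ord) {
    utils::combn(fit$fixed, ord, paste, collapse = ":", simplify = FALSE)
  }))
  rows <- lapply(terms, function(tm) {
    tf <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    L <- .type3_contrast(fit, tf)
    est <- drop(L %*% fit$beta)
    V <- L %*% fit$cov_beta %*% t(L)
    q <- nrow(L)
    Fstat <- drop(t(est) %*% solve(V, est)) / q
    # pooled Satterthwaite df over the eigen-contrasts of the term
    eg <- eigen(V, symmetric = TRUE)
    nus <- vapply(seq_len(q), function(i) {
      .satterthwaite_df(fit, drop(t(L) %*% eg$vectors[, i]), prep)
    }, numeric(1))
    if (q == 1L) {
      df2 <- nus[1L]
    } else {
      ok <- nus > 2
      E <- sum(nus[ok] / (nus[ok] - 2))
      df2 <- if (E > q) 2 * E / (E - q) else fit$df_resid
    }
    tibble::tibble(term = tm, F = Fstat, df1 = q, df2 = df2,
                   p = stats::pf(Fstat, q, df2, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

#' Tukey HSD pairwise comparisons
#'
#' All-pairs comparisons of `k` means using the studentized-range
#' distribution: for a pair with difference `d` and standard error of the
#' difference `se`, `q = |d| / (se / sqrt(2))` and
#' `p = P(Q_{k,df} > q)` via [stats::ptukey]. At `k = 2` this reduces
#' exactly to the two-sided t-test.
#'
#' @param means numeric vector of `k >= 2` (marginal or cell) means.
#' @param se_diff standard error(s) of pairwise differences: a scalar or a
#'   `k x k` matrix.
#' @param df denominator degrees of freedom (> 0).
#' @param k_family family size for the studentized range; defaults to
#'   `length(means)`.
#' @return A tibble with one row per unordered pair: `i`, `j`, `estimate`
#'   (`means[j] - means[i]`), `se`, `q`, `p_tukey`.
#' @export
tukey_hsd <- function(means, se_diff, df, k_family = length(means)) {
  k <- length(means)
  if (k < 2L) stop("need at least 2 means")
  if (df <= 0) stop("df must be positive")
  if (is.matrix(se_diff)) {
    stopifnot(all(dim(se_diff) == k))
  } else {
    se_diff <- matrix(se_diff, k, k)
  }
  pairs <- utils::combn(k, 2L)
  nm <- if (!is.null(names(means))) names(means) else as.character(seq_len(k))
  means <- as.numeric(means)
  est <- means[pairs[2L, ]] - means[pairs[1L, ]]
  se <- as.numeric(se_diff[cbind(pairs[1L, ], pairs[2L, ])])
  qstat <- abs(est) / (se / sqrt(2))
  tibble::tibble(
    i = nm[pairs[1L, ]], j = nm[pairs[2L, ]],
    estimate = est, se = se, q = qstat,
    p_tukey = stats::ptukey(qstat, nmeans = k_family, df = df,
                            lower.tail = FALSE)
  )
}

#' Per-strain cocaine-vs-saline responder classification
#'
#' For each strain, contrasts the cocaine and saline marginal means
#' (averaged over test days) from a fitted day x treatment x strain mixed
#' model. The standard error comes from the fixed-effect covariance, the
#' degrees of freedom from the Satterthwaite method, and the Tukey-adjusted
#' p-value treats the family as all strain x treatment marginal means
#' (`2 * n_strains` of them). A strain is a responder when the adjusted
#' p-value is below `alpha` and the cocaine - saline estimate is positive.
#' Strains observed in only one arm are marked inestimable.
#'
#' @param fit an [fit_lmm()] with factors day, treatment and strain.
#' @param alpha significance level for the responder flag.
#' @param treatment,strain,day names of the corresponding factors in `fit`.
#' @return A tibble: `strain`, `estimate`, `se`, `t`, `df`, `p_unadjusted`,
#'   `p_tukey`, `responder`, `estimable`.
#' @export
classify_responders <- function(fit, alpha = 0.05,
                                treatment = "treatment_group",
                                strain = "strain", day = "day") {
  stopifnot(inherits(fit, "lmm_fit"))
  stopifnot(all(c(treatment, strain, day) %in% fit$fixed))
  ti <- match(treatment, fit$fixed)
  tl <- fit$levels[[ti]]
  stopifnot(all(c("cocaine", "saline") %in% tl))
  # cell label component positions follow fit$fixed order
  parts <- strsplit(fit$cells, ":", fixed = TRUE)
  cell_of <- function(which_fac) vapply(parts, `[[`, "", match(which_fac, fit$fixed))
  c_strain <- cell_of(strain)
  c_treat <- cell_of(treatment)
  c_day <- cell_of(day)
  strains <- fit$levels[[match(strain, fit$fixed)]]
  k_family <- 2L * length(strains)
  prep <- .satter_prep(fit)

  rows <- lapply(strains, function(s) {
    coc <- which(c_strain == s & c_treat == "cocaine")
    sal <- which(c_strain == s & c_treat == "saline")
    shared <- intersect(c_day[coc], c_day[sal])
    if (length(shared) == 0L) {
      return(tibble::tibble(strain = s, estimate = NA_real_, se = NA_real_,
                            t = NA_real_, df = NA_real_,
                            p_unadjusted = NA_real_, p_tukey = NA_real_,
                            responder = FALSE, estimable = FALSE))
    }
    coc <- coc[c_day[coc] %in% shared]
    sal <- sal[c_day[sal] %in% shared]
    cvec <- numeric(length(fit$beta))
    cvec[coc] <- 1 / length(coc)
    cvec[sal] <- -1 / length(sal)
    est <- sum(cvec * fit$beta)
    se <- sqrt(drop(t(cvec) %*% fit$cov_beta %*% cvec))
    df <- .satterthwaite_df(fit, cvec, prep)
    tval <- est / se
    p_un <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    p_tk <- stats::ptukey(sqrt(2) * abs(tval), nmeans = k_family, df = df,
                          lower.tail = FALSE)
    tibble::tibble(strain = s, estimate = est, se = se, t = tval, df = df,
                   p_unadjusted = p_un, p_tukey = max(p_tk, p_un),
                   responder = p_tk < alpha && est > 0, estimable = TRUE)
  })
  do.call(rbind, rows)
}

#' Fixed-effects Type III ANOVA of a derived variable
#'
#' Cross-site replicability analysis: a fixed-effects ANOVA of a per-mouse
#' derived variable on the named factors (strain, sex, test site by
#' default) with all two-way interactions, Type III sums of squares (sum
#' contrasts via [car::Anova]) and residual denominator df. Factors with a
#' single observed level are dropped with a warning, as are interaction
#' terms made inestimable by empty cells.
#'
#' @param data per-mouse phenotype table.
#' @param response name of the response column.
#' @param factors character vector of factor column names.
#' @return A tibble: `term`, `F`, `df1`, `df2`, `p`.
#' @export
anova_fixed <- function(data, response, factors = c("strain", "sex", "site")) {
  stopifnot(all(c(response, factors) %in% names(data)))
  keep <- stats::complete.cases(data[c(response, factors)])
  dat <- data[keep, , drop = FALSE]
  for (f in factors) dat[[f]] <- factor(dat[[f]])
  single <- vapply(factors, function(f) nlevels(dat[[f]]) < 2L, logical(1))
  if (any(single)) {
    warning("dropping single-level factor(s): ",
            paste(factors[single], collapse = ", "))
    factors <- factors[!single]
  }
  if (length(factors) == 0L) stop("no factors with 2+ levels")
  form <- stats::as.formula(paste(
    response, "~",
    if (length(factors) > 1L) paste0("(", paste(factors, collapse = " + "), ")^2")
    else factors
  ))
  contr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  fit <- stats::lm(form, data = dat, contrasts = contr)
  if (anyNA(stats::coef(fit))) {
    # empty cells alias interaction coefficients; drop affected interactions
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    bad_terms <- unique(vapply(strsplit(aliased, ":", fixed = TRUE), function(s) {
      paste(sub("[0-9]+$", "", s), collapse = ":")
    }, ""))
    warning("empty cells alias term(s) ", paste(bad_terms, collapse = ", "),
            "; dropped from the model")
    keep_terms <- setdiff(attr(stats::terms(fit), "term.labels"), bad_terms)
    form <- stats::reformulate(keep_terms, response = response)
    fit <- stats::lm(form, data = dat, contrasts = contr)
  }
  a3 <- car::Anova(fit, type = "III")
  tab <- as.data.frame(a3)
  tm <- rownames(tab)
  keep_rows <- !tm %in% c("(Intercept)", "Residuals")
  df_res <- tab$Df[tm == "Residuals"]
  tibble::tibble(
    term = tm[keep_rows],
    F = tab[["F value"]][keep_rows],
    df1 = tab$Df[keep_rows],
    df2 = df_res,
    p = tab[["Pr(>F)"]][keep_rows]
  )
}
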