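---
title: "Models and methods behind ccsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ccsens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccsens)
```

`ccsens` analyzes cocaine-induced behavioral sensitization measured across a
panel of inbred mouse strains (Collaborative Cross strains plus their eight
founders). This vignette documents the statistical models, the synthetic
cohort generator, the numerical choices, and the design decisions that were
genuinely open — the things a maintainer or reviewer would want to know that
the reference pages do not cover.

## The protocol and the derived variables

Mice are tested in an open field on nine days of a 19-day protocol (days 1,
2, 3, 5, 7, 9, 11, 12, 19). Saline-arm mice receive saline every test day.
Drug-arm mice receive saline on days 1–2 (baseline), cocaine on days 3, 5,
7, 9, 11 (five consecutive exposures), saline on day 12 (a conditioned-
activation probe: does the test context alone now elevate activity?), and
cocaine again on day 19 after a drug-free week (expression of the sensitized
response). The response on every day is total distance (cm) in the 60
minutes after injection.

From each mouse's 9-day series we derive eight variables: the day-1 and
day-2 distances, habituation (D2 − D1), initial cocaine response (D3 − D2),
initial sensitization (D5 − D3), a sensitization AUC over the five
consecutive exposures, expression (D19 − D11), and conditioned activation
(D12 − D2). Difference scores are always later-day minus earlier-day. A
variable is missing if and only if one of its constituent days is missing,
and the reason is recorded per field.

**AUC rule.** "Area under the curve" across days 3–11 is ambiguous: one can
sum the five distances, integrate over calendar day (spacing 2), or
integrate over exposure index (spacing 1). `ccsens` defaults to the
trapezoidal rule over exposure index, `(D3 + D11)/2 + D5 + D7 + D9`, which
is the most common reading, is scale-consistent with the other variables,
and differs from calendar-day integration only by a constant factor of 2
(which cancels in every correlation and heritability ratio). The simple sum
is available via `auc_rule = "sum"` in `derive_variables()` /
`derive_cohort()` so both conventions can be compared against any deposited
values.

## Sex residualization and the mixed model

Sex differences are removed before modeling: `residualize_sex()` replaces
each observation with its residual from an OLS regression on intercept +
sex (equivalently, subtracts the sex-group mean). The residuals sum to zero
within each sex and the operation is idempotent. This keeps sex out of the
strain and treatment terms without spending factorial cells on it.

The central model for day-level distance is a three-way linear mixed model,

$$y_{msdt} = \mu_{d t s} + b_m + \varepsilon,\qquad
  b_m \sim N(0, \sigma^2_{mouse}),\quad
  \varepsilon \sim N(0, \sigma^2_e),$$

with a saturated day × treatment × strain mean structure and a random
intercept per mouse. `fit_lmm()` uses the cell-means parameterization
(`~ 0 + cell`): the fixed-effect vector *is* the set of
generalized-least-squares cell means, which makes Type III hypotheses
coding-independent by construction.

**Profiled REML.** With a single random intercept the restricted likelihood
can be profiled down to the scalar ratio
$\lambda = \sigma^2_{mouse}/\sigma^2_e$. For a given $\lambda$ the marginal
covariance within mouse $i$ is $\sigma^2_e (I + \lambda J_{n_i})$, whose
inverse square root is the per-group transform
$x \mapsto x - (1 - (1+\lambda n_i)^{-1/2})\,\bar x_i$; after transforming
$y$ and $X$, $\hat\beta$ and $\hat\sigma^2_e$ are ordinary least squares.
The profiled objective is minimized by Brent/golden-section search on
$\log\lambda$ over $[10^{-8}, 10^8]$ with tolerance $10^{-8}$, and the
result is compared against the $\lambda = 0$ boundary: a fit no better than
the boundary is reported as an exact $\hat\sigma^2_{mouse} = 0$ with a
`boundary` flag, never as a small positive value. Data with zero residual
variance (cell means explain everything) short-circuit to a `degenerate`
fit with exact cell means. The test suite checks the returned ratio against
a 64-point log-spaced grid and against `lme4::lmer`, and checks the
balanced one-way case against the closed-form ANOVA estimators
$\hat\sigma^2_e = MS_W$, $\hat\sigma^2_{between} = (MS_B - MS_W)/n$.

**Degrees of freedom.** F tests use Type III contrasts built by Kronecker
products over the factor levels and Satterthwaite denominator degrees of
freedom: for a single contrast $c$, $\nu = 2 f^2 / (g^\top V_\theta g)$
where $f = c^\top \widehat{\mathrm{cov}}(\hat\beta)\, c$, $g$ is its
numeric gradient in $\theta = (\sigma^2_{mouse}, \sigma^2_e)$, and
$V_\theta$ is the inverse observed information of the REML criterion
(central-difference Hessian). Multi-degree-of-freedom terms pool the
per-eigencontrast values the way lmerTest does. Satterthwaite rather than
Kenward-Roger was chosen because it is the default of the standard mixed-
model ANOVA tooling in this field; agreement with that tooling is verified
in the tests to ~4 significant figures on a factorial cohort. At the
boundary ($\hat\sigma^2_{mouse} = 0$) the denominator df collapse to the
classical residual df exactly. If the variance-parameter Hessian is
ill-conditioned the code falls back to residual df with a warning.

**Responders.** `classify_responders()` contrasts cocaine vs saline
marginal means per strain (averaged over the days both arms share). Tukey
HSD names an all-pairs procedure, so the adjustment family is taken as all
strain × treatment marginal means ($2a$ of them) while only the within-
strain pairs are reported; both the unadjusted and the Tukey-adjusted
p-values are emitted because published per-strain p-values do not state
which was used. A strain is a responder when the adjusted p-value is below
α and the contrast is positive. Studentized-range probabilities come from
`stats::ptukey`, which the tests validate against the two-sided t-test at
k = 2 (agreement ~10⁻¹²) and against a 10⁶-draw Monte-Carlo oracle of the
studentized range at (k = 3, df = 12).

## Broad-sense heritability

Heritability is computed in the cocaine arm only — genetic differences in
drug response are invisible in saline-treated animals — from the one-way
strain ANOVA of each per-mouse derived variable:

$$H^2 = \frac{MS_{strain}}{MS_{strain} + (\bar n - 1) MS_{resid}},$$

with $\bar n$ the *arithmetic mean* number of mice per strain (the
formula's literal reading; the unbalanced-design effective size
$n_0 = (N - \sum n_i^2/N)/(a-1)$ is used only where an actual variance
component is required). $H^2$ is strictly inside (0, 1) whenever both mean
squares are positive and $\bar n > 1$, is monotone in each mean square, and
is scale-invariant; all three are property-tested.

The standard error comes from a model-based parametric bootstrap: variance
components are extracted as $\hat\sigma^2_s = \max(0, (MS_{strain} -
MS_{resid})/n_0)$ (negative estimates clamped to zero, standard practice)
and $\hat\sigma^2_e = MS_{resid}$; each of the 1,000 replicates simulates
$y^*_{ij} = \bar y + s^*_i + e^*_{ij}$ preserving the observed per-strain
counts, and the SE is the standard deviation of the replicate $H^2$ values.
Whether such a bootstrap should re-simulate from the day-level mixed model
or the per-mouse one-way strain model is ambiguous in the field's usual
one-line descriptions; `ccsens` re-simulates from the one-way model because
the estimator itself operates on per-mouse derived variables, and the
calibration test (bootstrap SE vs the empirical SD of $H^2$ across 200
independent cohorts, agreement within 20%) supports that choice. Sexes are
pooled and raw (non-residualized) values are used, since residualization is
described only for the mixed-model ANOVA; callers can residualize first if
they prefer the alternative.

## Correlation structure and the autocorrelation mask

Strain-by-variable means (cocaine arm) feed pairwise-complete Pearson
correlations with two-sided p-values from $t = r\sqrt{(n-2)/(1-r^2)}$. A
derived variable shares raw data with the days it is computed from, so any
such correlation is an autocorrelation; the mask suppresses every pair of
variables whose day sets intersect (e.g., AUC × day 7, habituation × day 1)
while distinct single days are never masked and day-1 body weight is exempt.
For the standard 16-variable set this yields 22 masked and 98 reported
pairs, and a structural test verifies the full pattern cell by cell.
Bonferroni correction divides α by the number of *reported* pairs — the
visible cells — not all C(16, 2) pairs; the denominator is recorded in the
output's `n_tests` attribute. Pairwise-complete (not listwise) deletion is
used because strain coverage differs by variable; each pair reports its own
n, with a minimum of 3.

Cross-site replicability uses the same machinery per variable across the
strains measured at both sites, reporting r, n, df = n − 2 and p. The
fixed-effects strain × sex × site ANOVA (`anova_fixed`) is a standard
Type III linear-model ANOVA and delegates to `car::Anova` on an `lm` fit
with sum contrasts, dropping single-level factors and empty-cell-aliased
interactions with warnings.

## The synthetic cohort generator

`simulate_cohort()` generates the data structure the analyses assume:

* strain baseline effects $\sim N(0, \sigma^2_{strain})$ and strain
  sensitization slopes $\sim N(0, \sigma^2_{slope})$;
* per-mouse intercepts $\sim N(0, \sigma^2_{mouse})$ and day-level noise
  $\sim N(0, \sigma^2_e)$;
* in the drug arm, cocaine day $k$ ($k$ = 1..5, days 3–11) adds an acute
  effect plus a cumulative ramp $\sum_{j \le k} r_j$ plus the strain slope
  times $(k-1)$; day 12 adds the conditioned effect; day 19 adds the full
  ramp plus the expression effect. The ramp is cumulative on *exposure
  index*, not calendar day, because that is what reproduces the
  qualitatively distinct patterns seen across strains (differences in rate
  of sensitization vs maximal response) with few parameters;
* additive female−male and JAX−UNC shifts; distances floored at zero, with
  the truncation count reported because flooring slightly biases moments in
  extreme configurations.

The default configuration (shipped as
`inst/extdata/default_sim_config.json`) mirrors the shape of the target
study: 59 strains, 8 mice per strain per arm, nine test days, session
distances of a few thousand cm with an acute cocaine effect of ~3,000 cm
and strain/mouse/residual SDs of 1,000/500/1,000 cm. Published strain
surveys do not report within-strain variance components, so these values
were fixed once as field-plausible magnitudes chosen for test power, not
fitted to any deposit — the generator is a test harness, never an inference
target.

For balanced configs, `plugin_h2_expectation()` gives the analytic plug-in
value of the $H^2$ estimator for any derived variable: a variable with day
coefficients $c$ has between-strain variance $(\sum c)^2 \sigma^2_{strain}
+ (\sum_d c_d k_d)^2 \sigma^2_{slope}$ and within-strain variance
$(\sum c)^2 \sigma^2_{mouse} + \sum c_d^2\, \sigma^2_e$, and the estimator
targets $(\sigma^2_B + \sigma^2_W/n) / (\sigma^2_B + \sigma^2_W)$. This is
the oracle for the recovery test: over 200 cohorts of 50 strains × 10 mice
at $\sigma^2_B = \sigma^2_W = 1$ the mean $H^2$ must sit within 3
Monte-Carlo SEs of 0.55. (The mean of a ratio estimator carries an
$O(1/\mathrm{df})$ Jensen bias of about −0.005 at this size, well inside
the band.)

**What the generator does not emulate.** Real open-field data are
right-skewed and heteroscedastic, have occasional equipment dropouts,
batch/handler effects, and day-specific strain × environment interactions;
the generator is Gaussian, homoscedastic, and balanced by construction.
Passing tests therefore demonstrate that the estimators are implemented
correctly and are calibrated *under the assumed model* — they do not
validate the model against real mouse behavior.

## Numerical choices, problem sizes, limitations

* REML ratio search: Brent on $\log\lambda \in [\log 10^{-8}, \log 10^8]$,
  tolerance $10^{-8}$; boundary comparison at $\lambda = 0$ with slack
  $10^{-10}$; degenerate short-circuit when OLS RSS ≤ 10⁻¹⁴ of total SS.
* Satterthwaite gradients/Hessian: central differences with relative step
  $10^{-5}$ / $10^{-4}$; df capped at the residual df.
* Bootstrap replicates are simulated as matrices and reduced by grouped
  column sums, so 1,000 replicates of a 500-mouse cohort cost well under a
  second.
* Test-suite problem sizes (200 cohorts for recovery/calibration, 500 null
  replicates for type-I calibration, 10⁶ draws for the studentized-range
  oracle) were chosen so Monte-Carlo error is comfortably below each
  asserted tolerance while the whole suite stays in the low minutes on one
  CPU; the acceptance script's full-size mixed model (59 strains, 1,062
  cells, 8,496 rows) fits in about a minute.
* Known limitations: only a single random intercept (no crossed or
  day-level covariance structures); Type III contrasts require a complete
  day × treatment × strain factorial (strains missing an arm are excluded
  from contrasts and flagged inestimable rather than partially pooled); the
  heritability machinery assumes mice are exchangeable within strain and
  ignores day-level structure beyond the derived variable itself.
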