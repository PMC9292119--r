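---
title: "Marginal effects by parametric g-computation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal effects by parametric g-computation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmarginal)
```

## The estimand and the estimator

Most regression output answers a conditional question: what is the
association between exposure and outcome *holding the other covariates
fixed*? Public-health communication usually needs the marginal question
instead: if the whole study population were exposed versus unexposed, how
would the average outcome differ? For a binary exposure $A$, outcome $Y$
and covariates $W$, the target is the average treatment effect

$$\varphi_{ATE} = \sum_w \left[ E(Y \mid A = 1, W = w) - E(Y \mid A = 0, W
= w) \right] \Pr(W = w),$$

the contrast of counterfactual mean outcomes standardized to the joint
covariate distribution of the study population. `gmarginal` estimates it by
parametric g-computation, which is standardization carried out through a
fitted regression model so that continuous covariates pose no difficulty:

1. **Fit** a generalized linear model of the outcome on the exposure and
   covariates (family chosen by the outcome type, below).
2. **Predict** a counterfactual outcome for every observation under each
   exposure regime: the full table is cloned once per regime with the
   exposure column forced to that regime's value, and the fitted model is
   evaluated on the response scale.
3. **Average and contrast** the per-regime prediction means. For a binary
   outcome this yields marginal risks $p_0, p_1$ and from them the risk
   difference $p_1 - p_0$, risk ratio $p_1/p_0$, odds ratio
   $\frac{p_1/(1-p_1)}{p_0/(1-p_0)}$ and number needed to treat
   $1/(p_1-p_0)$; count and rate outcomes yield the incidence rate
   difference and ratio; continuous outcomes the mean difference.

Because the empirical covariate distribution does the averaging, the result
is a plug-in estimate of the marginal effect, not a coefficient read off
the model. For the odds ratio the two genuinely differ even without
confounding (non-collapsibility): the marginal OR sits closer to the null
than the conditional OR, and our tests verify that direction on an exact
enumeration oracle.

## Outcome families

| outcome type | family / link | measures returned |
|---|---|---|
| `binary` | binomial / logit | RD, RR, OR, NNT |
| `count`, `rate` | Poisson / log | IRD, IRR |
| `count_nb`, `rate_nb` | negative binomial / log | IRD, IRR |
| `continuous` | gaussian / identity | mean difference |

Fits are maximum likelihood by IRLS with a relative-deviance tolerance of
`1e-8` within 100 iterations — the common GLM defaults, stated here because
the exactness tolerances in our tests depend on them. The negative binomial
uses the variance function $\mu + \mu^2/\theta$ with $\theta$ estimated
internally by alternating GLM and ML-dispersion updates (via
`MASS::glm.nb`); on equidispersed data $\theta \to \infty$ and the
coefficients reproduce the Poisson fit, a limit we assert in tests.
`count` and `rate` share the same machinery and differ only in whether a
person-time offset is required: `rate` demands one, `count` defaults to
unit exposure time. The offset column is supplied on the linear scale and
enters the model as its natural log; at prediction time it is replaced by
the `rate_multiplier`, so counterfactual rates come out directly on the
reporting denominator (e.g. `365.25 * 100` for rates per 100 person-years
when person-time is recorded in days).

Separation (unbounded coefficients, $|\hat\beta| > 20$ on the link scale)
triggers a warning rather than an error. This is deliberate: sparse strata
separate transiently in bootstrap resamples, and the resample-failure
policy below is the right place to deal with them, not a hard stop on the
whole analysis.

## Exposures, subgroups, interactions

A categorical exposure uses its first level as the referent (levels sort
ascending unless the user supplies an order), and an $L$-level exposure
yields $L-1$ contrasts against the referent, all sharing one bootstrap
stream per replicate. A numeric exposure is transformed to $(x - c)/s$:
$c$ is the sample mean by default (or a user-supplied number, or 0), $s$
is the `exposure_scalar`. The single contrast reported is $c \to c + s$,
and the output labels those raw endpoints deliberately — with a nonlinear
link the risk difference and ratio for a one-unit step depend on where the
step starts, so the estimate must not be read as applying across the whole
exposure range.

User formulas are additive only; `*` and `:` are rejected. The one
interaction the model ever contains is added internally when a `subgroup`
is requested: terms become exposure + subgroup + exposure:subgroup +
covariates, a single model fit on the full data. Counterfactual prediction
and averaging are then performed within each subgroup's rows, i.e. each
subgroup's effects are standardized to its own covariate distribution.
That choice (rather than standardizing every subgroup to the total
population) matches how sex-specific baseline rates are usually reported
and is what makes additive effect-measure modification legible: the
subgroup IRDs are contrasts of rates each sex would actually experience.
If the subgroup also appears in the covariate list it enters the model
once. When the subgroup interaction saturates the model, the within-stratum
estimates coincide exactly with refitting each stratum separately — a
property the tests exploit as an oracle.

## Bootstrap inference

Standard errors of the underlying GLM coefficients do not apply to the
standardized estimates, so all intervals come from a percentile bootstrap:
the point estimate is computed on the original data, the whole three-step
procedure is repeated on `n_boot` resamples (default `R = 200` for
exploration; 1000 is recommended for final analyses), and the 95% interval
is the 2.5th and 97.5th percentile of the replicate estimates.
Conventions worth stating exactly:

* **Percentile rule.** Linear interpolation between order statistics at
  $h = (n-1)p + 1$ (`stats::quantile` type 7). The convention is echoed in
  the JSON report because last-digit differences between implementations
  trace to exactly this choice.
* **Ratio measures** (RR, OR, IRR) have their percentiles taken on the
  natural-log scale and exponentiated; their bootstrap distributions are
  approximately log-symmetric, and the diagnostics plot them on that scale
  for the same reason. Because log is monotone this equals raw-scale
  percentiles whenever the interpolation does not straddle two order
  statistics, which the tests assert exactly at draw counts where
  $(n-1)p + 1$ is an integer.
* **NNT** gets a point estimate, never an interval: interval methods for
  it are not standardized, and it is troublesome to interpret when the RD
  interval crosses the null. A negative RD is reported as a number needed
  to harm with the magnitude $|1/\mathrm{RD}|$; an RD of exactly zero
  yields an infinite sentinel rather than an error.
* **Centering.** A numeric exposure is centered once, on the original
  data, and every replicate reuses that value; otherwise each resample
  would quietly estimate a slightly different contrast.
* **Failed replicates** (non-convergence, a resample missing an exposure
  level) are dropped and counted in `n_boot_failed`; silently retrying
  would bias the bootstrap distribution. More than 10% failures aborts
  with a diagnostic, since at that point the percentile interval no longer
  summarizes the intended distribution.
* **Clustered data** resample whole clusters with replacement, each drawn
  cluster contributing all member rows, so resampled tables may differ in
  row count. For nesting deeper than one level, `point_estimate()` is
  exported so users can assemble their own resampling scheme.
* **Reproducibility.** One root seed draws one sub-seed per replicate up
  front; each replicate seeds its own RNG stream. Results are therefore
  identical for any `parallel_workers` count and any scheduling order, a
  contract the tests assert bit-for-bit.

## The synthetic cohort generator

`generative_model()` / `generate_cohort()` produce Framingham-like cohorts
with known truth, and `true_marginal_effects()` computes the true marginal
effects by a potential-outcome Monte-Carlo oracle (draw covariates,
evaluate the true mean outcome under each exposure level, average), with
delta-method Monte-Carlo standard errors. Default parameters were fixed
once to emulate the regime of a classic cardiovascular cohort analysis:
binary exposure with ~10% prevalence driven by mixed continuous/binary
covariates (age, sex, BMI, smoking, hypertension), binary outcome
incidence ~40% under moderate confounding — high enough that the odds
ratio visibly fails to approximate the risk ratio — baseline rates near 2
events per 100 person-years with person-time uniform on 1000–8766 days,
and negative binomial dispersion $\theta = 1.5$ so overdispersion is
detectable at moderate sample sizes. Intercepts were chosen from
closed-form logit targets (e.g. $\mathrm{expit}(-2.4) \approx 8\%$ rising
to ~10% with covariate variance) and left alone thereafter.

What the generator does *not* emulate: missingness, measurement error,
informative censoring or any time-varying structure, selection into the
cohort, and real covariate dependence (covariates are drawn
independently). Passing tests on these cohorts therefore demonstrate
correctness of the estimator under a correctly specified time-fixed model,
not robustness to the ways real cohort data are messy.

## Validation design and simulation sizes

The test suite separates exact oracles from stochastic ones:

* **Exact:** hand-coded direct standardization by cell counting on tables
  where the additive logistic model is saturated in effect; a hand-coded
  ML oracle (BFGS + Newton on the explicit likelihood) for an 8-row
  logistic example, agreed to 1e-6; score-equation residuals below 1e-6;
  closed-form 2x2 and two-group rate examples; percentile endpoints against
  an independent sort-and-interpolate implementation.
* **Stochastic:** estimator bias at $n = 5{,}000$ over 200 replicates
  within 2 Monte-Carlo standard errors of zero; 95% interval coverage of
  the true marginal risk difference in $[0.90, 0.98]$ at $n = 500$,
  $R = 200$, 200 simulations. These sizes are the package's simulation
  design: large enough that a miscoded estimator fails decisively, small
  enough to run routinely.

Degenerate inputs are handled loudly: empty tables, single-level
exposures, aliased designs, non-positive offsets and character exposures
are errors; missing values in referenced columns are rejected with a count
unless `drop_missing = TRUE` is set, in which case the number of dropped
rows is reported — listwise deletion is never silent.

## Known limitations

Only time-fixed exposures: no time-varying confounding, mediation,
inverse-probability weighting or doubly-robust estimation. Bootstrap
intervals are mildly conservative relative to closed-form alternatives
when those are valid, at the gain of one uniform inference path across all
measures. Continuous-exposure contrasts are local by construction, as
discussed above. The only bootstrap flavor offered is the percentile
method; BCa and studentized variants are deliberately out of scope.
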