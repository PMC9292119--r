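#' Define a synthetic cohort generative model
#'
#' Describes a Framingham-like time-fixed cohort with known generating
#' coefficients, so estimates can be checked against exact truths. Baseline
#' covariates are drawn as: age ~ Normal(50, 8.6) years, sex ~
#' Bernoulli(0.45), bmi ~ Normal(25.8, 4.1) kg/m2, smoke ~ Bernoulli(0.49),
#' hyperten ~ Bernoulli(0.31). A binary exposure follows a logistic model
#' in the covariates, and the outcome follows a GLM of the requested type
#' with the given link-scale coefficients. Continuous covariates enter all
#' linear predictors centered (age - 50, bmi - 25.8), so each intercept is
#' the link-scale value for a covariate-average unexposed subject.
#'
#' Default coefficients put exposure prevalence near 10% and binary-outcome
#' incidence near 40% with moderate confounding — a regime in which the
#' marginal odds ratio visibly exceeds the risk ratio. Rate outcomes use a
#' person-time column in days drawn uniformly on `person_time`, with a
#' baseline rate near 2 events per 100 person-years.
#'
#' @param n Number of observations.
#' @param outcome_type Outcome family keyword (see [analysis_spec()]).
#' @param exposure_coefs Named link-scale (logit) coefficients for the
#'   exposure model: `intercept`, `age`, `sex`, `bmi`, `smoke`, `hyperten`.
#' @param outcome_coefs Same names plus `exposure`, on the outcome link
#'   scale (logit, log, or identity).
#' @param theta Negative binomial dispersion (variance \eqn{\mu + \mu^2 /
#'   \theta}) for `count_nb`/`rate_nb`. Default 1.5 (marked
#'   overdispersion).
#' @param sigma Residual SD for `continuous`.
#' @param person_time Length-2 range (days) of the uniform person-time law
#'   for rate outcomes.
#' @param n_clusters If > 0, observations are assigned to this many
#'   equal-size clusters sharing a Normal(0, `cluster_sd`) random intercept
#'   on the outcome link scale (for cluster-bootstrap tests).
#' @param cluster_sd Cluster random-intercept SD.
#' @return A `gen_model` list.
#' @export
generative_model <- function(n = 4240,
                             outcome_type = c("binary", "count", "count_nb",
                                              "rate", "rate_nb",
                                              "continuous"),
                             exposure_coefs = NULL, outcome_coefs = NULL,
                             theta = 1.5, sigma = 5,
                             person_time = c(1000, 8766),
                             n_clusters = 0, cluster_sd = 0) {
  outcome_type <- match.arg(outcome_type)
  if (is.null(exposure_coefs))
    exposure_coefs <- c(intercept = -2.4, age = 0.05, sex = -0.3,
                        bmi = 0.06, smoke = 0.1, hyperten = 0.6)
  if (is.null(outcome_coefs))
    outcome_coefs <- switch(outcome_type,
      binary = c(intercept = -0.9, exposure = 1.5, age = 0.08, sex = -0.9,
                 bmi = 0.04, smoke = 0.5, hyperten = 0.8),
      count = , count_nb = c(intercept = 0.7, exposure = 0.5, age = 0.02,
                             sex = -0.3, bmi = 0.01, smoke = 0.2,
                             hyperten = 0.3),
      rate = , rate_nb = c(intercept = -9.9, exposure = 0.65, age = 0.06,
                           sex = -0.7, bmi = 0.02, smoke = 0.4,
                           hyperten = 0.6),
      continuous = c(intercept = 25, exposure = 2.5, age = 0.1, sex = -1,
                     bmi = 0.2, smoke = 0.5, hyperten = 1))
  need <- c("intercept", "age", "sex", "bmi", "smoke", "hyperten")
  stopifnot(all(need %in% names(exposure_coefs)),
            all(c(need, "exposure") %in% names(outcome_coefs)),
            theta > 0, sigma > 0, length(person_time) == 2L,
            all(person_time > 0), n_clusters >= 0, cluster_sd >= 0)
  structure(list(n = as.integer(n), outcome_type = outcome_type,
                 exposure_coefs = exposure_coefs,
                 outcome_coefs = outcome_coefs, theta = theta, sigma = sigma,
                 person_time = sort(as.numeric(person_time)),
                 n_clusters = as.integer(n_clusters),
                 cluster_sd = cluster_sd),
            class = "gen_model")
}

draw_covariates <- function(n) {
  data.frame(age = stats::rnorm(n, 50, 8.6),
             sex = stats::rbinom(n, 1, 0.45),
             bmi = stats::rnorm(n, 25.8, 4.1),
             smoke = stats::rbinom(n, 1, 0.49),
             hyperten = stats::rbinom(n, 1, 0.31))
}

covariate_lp <- function(cov, coefs) {
  coefs[["intercept"]] +
    coefs[["age"]] * (cov$age - 50) + coefs[["sex"]] * cov$sex +
    coefs[["bmi"]] * (cov$bmi - 25.8) + coefs[["smoke"]] * cov$smoke +
    coefs[["hyperten"]] * cov$hyperten
}

expit <- function(x) 1 / (1 + exp(-x))

#' Generate a synthetic cohort
#'
#' Draws one cohort from a [generative_model()]. Columns are named and
#' typed to feed [analysis_spec()] directly: covariates `age`, `sex`,
#' `bmi`, `smoke`, `hyperten`; exposure `exposed` (0/1); outcome `y`;
#' person-time `ptime` (days, rate outcomes only); `cluster` when the
#' model has clusters.
#'
#' @param model A `gen_model`.
#' @param seed Integer seed; the same seed reproduces the same table.
#' @return A `cohort_table` with `model$n` rows (an error for `n = 0`,
#'   since an empty table is not a valid cohort).
#' @export
generate_cohort <- function(model, seed) {
  stopifnot(inherits(model, "gen_model"))
  set.seed(as.integer(seed))
  n <- model$n
  cov <- draw_covariates(n)
  a <- stats::rbinom(n, 1, expit(covariate_lp(cov, model$exposure_coefs)))
  lp <- covariate_lp(cov, model$outcome_coefs) +
    model$outcome_coefs[["exposure"]] * a

  cl <- NULL
  if (model$n_clusters > 0) {
    cl <- rep_len(seq_len(model$n_clusters), n)
    b <- stats::rnorm(model$n_clusters, 0, model$cluster_sd)
    lp <- lp + b[cl]
  }

  tt <- model$outcome_type
  df <- cov
  df$exposed <- a
  if (tt %in% c("rate", "rate_nb")) {
    df$ptime <- stats::runif(n, model$person_time[1], model$person_time[2])
    mu <- exp(lp) * df$ptime
    df$y <- if (tt == "rate") stats::rpois(n, mu)
      else stats::rnbinom(n, size = model$theta, mu = mu)
  } else {
    df$y <- switch(tt,
      binary = stats::rbinom(n, 1, expit(lp)),
      count = stats::rpois(n, exp(lp)),
      count_nb = stats::rnbinom(n, size = model$theta, mu = exp(lp)),
      continuous = stats::rnorm(n, lp, model$sigma))
  }
  if (!is.null(cl)) df$cluster <- cl
  types <- c(age = "numeric", sex = "binary01", bmi = "numeric",
             smoke = "binary01", hyperten = "binary01",
             exposed = "binary01", y = if (tt == "binary") "binary01"
             else "numeric")
  if (!is.null(df$ptime)) types["ptime"] <- "numeric"
  if (!is.null(cl)) types["cluster"] <- "numeric"
  cohort_table(df, column_types = types)
}

#' True marginal effects of a generative model
#'
#' Monte-Carlo potential-outcome oracle: draws `n_mc` covariate vectors
#' from the model's covariate laws, evaluates the true mean outcome under
#' exposure forced to 1 and to 0 for every draw, averages, and forms the
#' same effect measures the estimator reports, together with Monte-Carlo
#' standard errors (delta method for ratio measures). This integrates over
#' the covariate distribution exactly as the g-computation target does, so
#' estimator bias can be measured against it.
#'
#' @param model A `gen_model` with a binary exposure law.
#' @param n_mc Number of Monte-Carlo covariate draws.
#' @param seed Seed for the oracle draws.
#' @param rate_multiplier Reporting denominator for rate/count outcomes
#'   (match the analysis spec's value).
#' @return A `true_effects` list: `measures` (named vector), `se`
#'   (Monte-Carlo SEs; `NA` for NNT), `marginal_means` (referent first),
#'   `n_mc`.
#' @export
true_marginal_effects <- function(model, n_mc = 2e5, seed = 1,
                                  rate_multiplier = 1) {
  stopifnot(inherits(model, "gen_model"))
  set.seed(as.integer(seed))
  cov <- draw_covariates(n_mc)
  lp0 <- covariate_lp(cov, model$outcome_coefs)
  if (model$cluster_sd > 0)
    lp0 <- lp0 + stats::rnorm(n_mc, 0, model$cluster_sd)
  lp1 <- lp0 + model$outcome_coefs[["exposure"]]

  tt <- model$outcome_type
  mu <- function(lp) switch(tt,
    binary = expit(lp),
    continuous = lp,
    exp(lp) * rate_multiplier)  # count and rate families
  mu1 <- mu(lp1); mu0 <- mu(lp0)
  m1 <- mean(mu1); m0 <- mean(mu0)
  measures <- counterfactual_contrast(m1, m0, tt)

  v1 <- stats::var(mu1) / n_mc
  v0 <- stats::var(mu0) / n_mc
  c01 <- stats::cov(mu1, mu0) / n_mc
  se <- vapply(names(measures), function(msr) {
    switch(msr,
      risk_difference = , rate_difference = , mean_difference =
        sqrt(v1 + v0 - 2 * c01),
      risk_ratio = , rate_ratio = {
        slog <- sqrt(v1 / m1^2 + v0 / m0^2 - 2 * c01 / (m1 * m0))
        measures[[msr]] * slog
      },
      odds_ratio = {
        d1 <- 1 / (m1 * (1 - m1)); d0 <- 1 / (m0 * (1 - m0))
        slog <- sqrt(v1 * d1^2 + v0 * d0^2 - 2 * c01 * d1 * d0)
        measures[[msr]] * slog
      },
      NA_real_)
  }, numeric(1))

  structure(list(measures = measures, se = se,
                 marginal_means = c(referent = m0, index = m1), n_mc = n_mc),
            class = "true_effects")
}

#' @export
print.true_effects <- function(x, ...) {
  cat("True marginal effects (Monte-Carlo oracle, n_mc = ", x$n_mc, ")\n",
      sep = "")
  print(data.frame(measure = names(x$measures), value = unname(x$measures),
                   mc_se = unname(x$se)), row.names = FALSE)
  invisible(x)
}
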