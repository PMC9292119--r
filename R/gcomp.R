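#' G-computation point estimate
#'
#' Runs the three steps of parametric g-computation on one dataset:
#' (1) fit the outcome regression on the observed data; (2) predict a
#' counterfactual outcome for every observation under each exposure regime,
#' i.e. clone the full table once per regime with the exposure column forced
#' to that regime's value (and, for count/rate outcomes, the person-time
#' offset set to the rate multiplier); (3) average the predictions per
#' regime and contrast the averages. The resulting effects are marginal —
#' standardized to the joint covariate distribution of the analysis
#' population (or, with a subgroup, of each subgroup's members).
#'
#' With a categorical exposure of L levels, the L-1 non-referent levels are
#' each contrasted against the referent. With a numeric exposure the single
#' contrast is `center -> center + exposure_scalar` on the raw exposure
#' scale; the report labels the raw endpoints because difference and ratio
#' measures from a nonlinear model do not transport across the whole range
#' of a continuous exposure.
#'
#' @param table A `cohort_table` (validated or not).
#' @param spec An [analysis_spec()].
#' @param centering_value Optional numeric-exposure centering constant
#'   overriding the sample mean (the bootstrap passes the original-data
#'   value so all resamples share one centering).
#' @return A `gcomp_point` list: `estimates` (data.frame with columns
#'   `group`, `contrast`, `measure`, `estimate`), `marginal_means`,
#'   `predictions` (n_obs x n_regimes matrix of response-scale
#'   counterfactual predictions), `model` (an `outcome_fit`), `centering`,
#'   and the validated `spec`.
#' @export
point_estimate <- function(table, spec, centering_value = NULL) {
  v <- validate_spec(table, spec)
  table <- v$table; spec <- v$spec
  design <- build_design(table, spec, centering_value = centering_value)
  model <- fit_outcome_model(design, spec$outcome_type)

  regimes <- design$regimes
  n <- nrow(design$data)
  preds <- matrix(NA_real_, n, length(regimes),
                  dimnames = list(NULL, design$regime_labels))
  offset_override <- if (design$has_offset) spec$rate_multiplier else NULL
  for (k in seq_along(regimes)) {
    nd <- design$data
    nd$.A <- if (is.factor(nd$.A))
      factor(regimes[k], levels = levels(nd$.A)) else regimes[k]
    preds[, k] <- predict_response(model, nd, offset_override)
  }

  groups <- if (is.null(spec$subgroup)) list(overall = seq_len(n)) else {
    lv <- design$subgroup_levels
    idx <- lapply(lv, function(l) which(design$data$.S == l))
    names(idx) <- paste0(spec$subgroup, "=", lv)
    idx
  }

  mm <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(group = g, regime = design$regime_labels,
               mean = colMeans(preds[groups[[g]], , drop = FALSE]),
               row.names = NULL)
  }))

  est <- do.call(rbind, lapply(names(groups), function(g) {
    m <- mm$mean[mm$group == g]
    do.call(rbind, lapply(seq_along(regimes)[-1], function(k) {
      cf <- counterfactual_contrast(m[k], m[1], spec$outcome_type)
      data.frame(group = g,
                 contrast = paste(design$regime_labels[k], "vs",
                                  design$regime_labels[1]),
                 measure = names(cf), estimate = unname(cf),
                 row.names = NULL)
    }))
  }))

  structure(list(estimates = est, marginal_means = mm, predictions = preds,
                 model = model, centering = design$centering,
                 regime_labels = design$regime_labels, spec = spec),
            class = "gcomp_point")
}

#' Marginal effect measures from two counterfactual means
#'
#' Closed-form contrasts of two marginal mean outcomes. For a binary
#' outcome with means \eqn{p_1, p_0}: risk difference \eqn{p_1 - p_0},
#' risk ratio \eqn{p_1/p_0}, odds ratio
#' \eqn{[p_1/(1-p_1)]/[p_0/(1-p_0)]} and number needed to treat
#' \eqn{1/(p_1-p_0)} (reported as `Inf` when the risk difference is exactly
#' zero; a negative value means number needed to harm). Count/rate outcomes
#' yield the incidence rate difference and ratio on the rate-multiplier
#' scale; continuous outcomes the mean difference. A referent mean of zero
#' makes ratio measures undefined (`NA`).
#'
#' @param m1 Index-regime marginal mean.
#' @param m0 Referent-regime marginal mean.
#' @param outcome_type Outcome family keyword.
#' @return Named numeric vector of effect measures.
#' @export
counterfactual_contrast <- function(m1, m0, outcome_type) {
  switch(outcome_type,
    binary = {
      rd <- m1 - m0
      rr <- if (m0 == 0) NA_real_ else m1 / m0
      or <- if (m0 %in% c(0, 1) || m1 %in% c(0, 1)) NA_real_
        else (m1 / (1 - m1)) / (m0 / (1 - m0))
      c(risk_difference = rd, risk_ratio = rr, odds_ratio = or,
        nnt = if (rd == 0) Inf else 1 / rd)
    },
    count = , count_nb = , rate = , rate_nb = c(
      rate_difference = m1 - m0,
      rate_ratio = if (m0 == 0) NA_real_ else m1 / m0),
    continuous = c(mean_difference = m1 - m0),
    stop("unknown outcome_type", call. = FALSE))
}

# flatten an estimates data.frame to a named vector in stable order
estimate_vector <- function(pt) {
  stats::setNames(pt$estimates$estimate,
                  paste(pt$estimates$group, pt$estimates$contrast,
                        pt$estimates$measure, sep = " | "))
}

#' @export
print.gcomp_point <- function(x, ...) {
  cat("G-computation point estimate (", x$spec$outcome_type, " outcome)\n\n",
      sep = "")
  print(format_estimates(x$estimates), row.names = FALSE)
  cat("\nMarginal mean outcomes:\n")
  print(x$marginal_means, row.names = FALSE)
  invisible(x)
}

measure_labels <- c(
  risk_difference = "Risk Difference", risk_ratio = "Risk Ratio",
  odds_ratio = "Odds Ratio", nnt = "Number Needed to Treat",
  rate_difference = "Incidence Rate Difference",
  rate_ratio = "Incidence Rate Ratio",
  mean_difference = "Mean Difference")

ratio_measures <- c("risk_ratio", "odds_ratio", "rate_ratio")

format_estimates <- function(est) {
  out <- est
  out$measure <- ifelse(out$measure == "nnt" & out$estimate < 0,
                        "Number Needed to Harm",
                        unname(measure_labels[out$measure]))
  out$estimate <- ifelse(grepl("Number Needed", out$measure),
                         abs(out$estimate), out$estimate)
  out
}
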