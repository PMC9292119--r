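test_that("no-covariate estimates equal textbook 2x2 formulas", {
  ct <- make_2x2_cohort(30, 100, 20, 100)
  pt <- point_estimate(ct, analysis_spec(outcome = "y", exposure = "a"))
  est <- setNames(pt$estimates$estimate, pt$estimates$measure)
  expect_equal(unname(est["risk_difference"]), 0.10, tolerance = 1e-8)
  expect_equal(unname(est["risk_ratio"]), 1.5, tolerance = 1e-8)
  expect_equal(unname(est["odds_ratio"]), (0.3 / 0.7) / (0.2 / 0.8),
               tolerance = 1e-8)
  expect_equal(unname(est["nnt"]), 10, tolerance = 1e-7)
  # marginal means are the sample proportions
  expect_equal(sort(pt$marginal_means$mean), c(0.2, 0.3), tolerance = 1e-8)
})

test_that("two-group rate analysis yields crude IRD and IRR on the multiplier scale", {
  rt <- make_rate_cohort(15, 500, 10, 800)
  sp <- analysis_spec(outcome = "y", exposure = "a", offset = "pt",
                      outcome_type = "rate", rate_multiplier = 100)
  pt <- point_estimate(rt, sp)
  est <- setNames(pt$estimates$estimate, pt$estimates$measure)
  expect_equal(unname(est["rate_difference"]), 1.75, tolerance = 1e-8)
  expect_equal(unname(est["rate_ratio"]), 2.4, tolerance = 1e-8)
  # rate ratio invariant to the multiplier; difference scales linearly
  sp2 <- analysis_spec(outcome = "y", exposure = "a", offset = "pt",
                       outcome_type = "rate", rate_multiplier = 1000)
  est2 <- setNames(point_estimate(rt, sp2)$estimates$estimate,
                   pt$estimates$measure)
  expect_equal(unname(est2["rate_ratio"]), unname(est["rate_ratio"]),
               tolerance = 1e-10)
  expect_equal(unname(est2["rate_difference"]),
               10 * unname(est["rate_difference"]), tolerance = 1e-8)
})

test_that("g-computation equals direct standardization on a logit-additive table", {
  # cell probabilities chosen logit-additive, counts chosen so empirical
  # proportions hit them exactly: the additive model is then saturated in
  # effect, and plug-in g-computation must equal explicit cell counting
  cells <- data.frame(a = c(0, 1, 0, 1), w = c(0, 0, 1, 1),
                      n = c(10, 10, 20, 20), e = c(5, 8, 4, 10))
  df <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    with(cells[i, ], data.frame(a = rep(a, n), w = rep(w, n),
                                y = rep(c(1, 0), c(e, n - e))))
  }))
  v <- validate_spec(cohort_table(df),
                     analysis_spec(outcome = "y", exposure = "a",
                                   covariates = "w"))
  pt <- point_estimate(v$table, v$spec)
  m1 <- oracle_direct_standardization(df$a, df$w, df$y, 1)
  m0 <- oracle_direct_standardization(df$a, df$w, df$y, 0)
  mm <- pt$marginal_means$mean
  expect_equal(mm, c(m0, m1), tolerance = 1e-8)
  est <- setNames(pt$estimates$estimate, pt$estimates$measure)
  expect_equal(unname(est["risk_difference"]), m1 - m0, tolerance = 1e-8)
  expect_equal(unname(est["risk_ratio"]), m1 / m0, tolerance = 1e-8)
})

test_that("8-row logistic example matches the brute-force standardization oracle", {
  df <- eight_row_fixture()
  pt <- point_estimate(cohort_table(df),
                       analysis_spec(outcome = "y", exposure = "a",
                                     covariates = "w"))
  b <- oracle_logistic_fit(cbind(1, df$a, df$w), df$y)
  m1 <- mean(oracle_expit(cbind(1, 1, df$w) %*% b))
  m0 <- mean(oracle_expit(cbind(1, 0, df$w) %*% b))
  expect_equal(pt$marginal_means$mean, c(m0, m1), tolerance = 1e-6)
  est <- setNames(pt$estimates$estimate, pt$estimates$measure)
  expect_equal(unname(est["risk_difference"]), m1 - m0, tolerance = 1e-6)
  expect_equal(unname(est["risk_ratio"]), m1 / m0, tolerance = 1e-6)
  expect_equal(unname(est["odds_ratio"]),
               (m1 / (1 - m1)) / (m0 / (1 - m0)), tolerance = 1e-6)
  # frozen oracle values
  expect_equal(unname(est[c("risk_difference", "risk_ratio", "odds_ratio")]),
               c(0.25, 1.5, 3.0), tolerance = 1e-6)
})

test_that("relabelling the referent flips the contrast", {
  gm <- generative_model(n = 500)
  ct <- generate_cohort(gm, seed = 31)
  sp <- synth_spec()
  fwd <- point_estimate(ct, sp)
  ct2 <- ct
  ct2$exposed <- factor(ct2$exposed, levels = c(1, 0))  # swap referent
  attr(ct2, "col_types")["exposed"] <- "categorical"
  rev <- point_estimate(ct2, sp)
  f <- setNames(fwd$estimates$estimate, fwd$estimates$measure)
  r <- setNames(rev$estimates$estimate, rev$estimates$measure)
  expect_equal(unname(r["risk_difference"]), -unname(f["risk_difference"]),
               tolerance = 1e-8)
  expect_equal(unname(r["risk_ratio"]), 1 / unname(f["risk_ratio"]),
               tolerance = 1e-8)
  expect_equal(unname(r["odds_ratio"]), 1 / unname(f["odds_ratio"]),
               tolerance = 1e-8)
})

test_that("collapsibility ordering OR >= RR >= 1 holds when RD > 0", {
  for (seed in c(3, 17, 42)) {
    ct <- generate_cohort(generative_model(n = 1500), seed = seed)
    est <- setNames(point_estimate(ct, synth_spec())$estimates$estimate,
                    c("risk_difference", "risk_ratio", "odds_ratio", "nnt"))
    expect_gt(est[["risk_difference"]], 0)
    expect_gte(est[["odds_ratio"]], est[["risk_ratio"]])
    expect_gte(est[["risk_ratio"]], 1)
  }
})

test_that("categorical exposures with L levels give L-1 contrasts vs the referent", {
  set.seed(8)
  n <- 600
  df <- data.frame(dose = factor(sample(c("none", "low", "high"), n, TRUE),
                                 levels = c("none", "low", "high")))
  p <- c(none = 0.2, low = 0.3, high = 0.45)[as.character(df$dose)]
  df$y <- rbinom(n, 1, p)
  pt <- point_estimate(cohort_table(df),
                       analysis_spec(outcome = "y", exposure = "dose"))
  expect_identical(nrow(pt$estimates), 8L)  # 2 contrasts x 4 measures
  expect_setequal(unique(pt$estimates$contrast),
                  c("dose=low vs dose=none", "dose=high vs dose=none"))
  # with no covariates each contrast is the crude comparison
  crude <- tapply(df$y, df$dose, mean)
  rd <- pt$estimates$estimate[pt$estimates$measure == "risk_difference"]
  expect_equal(sort(rd),
               sort(unname(c(crude["low"] - crude["none"],
                             crude["high"] - crude["none"]))),
               tolerance = 1e-8)
})

test_that("a null contrast reports NNT as an infinite sentinel, not an error", {
  # exactly equal marginal means: the sentinel, no divide-by-zero crash
  null_cf <- counterfactual_contrast(0.5, 0.5, "binary")
  expect_identical(null_cf[["nnt"]], Inf)
  expect_identical(null_cf[["risk_difference"]], 0)
  expect_identical(null_cf[["risk_ratio"]], 1)
  expect_identical(null_cf[["odds_ratio"]], 1)
  # a ratio with a zero referent is undefined, not an error
  expect_true(is.na(counterfactual_contrast(0.3, 0, "rate")[["rate_ratio"]]))
  # fitted null 2x2: risk difference is zero to rounding, NNT explodes
  ct <- make_2x2_cohort(20, 100, 20, 100)
  est <- setNames(point_estimate(ct, analysis_spec(outcome = "y",
                                                   exposure = "a"))$estimates$estimate,
                  c("risk_difference", "risk_ratio", "odds_ratio", "nnt"))
  expect_lt(abs(est[["risk_difference"]]), 1e-10)
  expect_gt(abs(est[["nnt"]]), 1e10)
  expect_equal(est[["risk_ratio"]], 1, tolerance = 1e-8)
})

test_that("subgroup analysis fits one interaction model and standardizes within stratum", {
  set.seed(12)
  n <- 800
  df <- data.frame(a = rbinom(n, 1, 0.5), s = rbinom(n, 1, 0.5))
  df$y <- rbinom(n, 1, oracle_expit(-1 + 0.8 * df$a + 0.5 * df$s -
                                      0.6 * df$a * df$s))
  sp <- analysis_spec(outcome = "y", exposure = "a", subgroup = "s")
  pt <- point_estimate(cohort_table(df), sp)
  expect_setequal(unique(pt$estimates$group), c("s=0", "s=1"))
  # the interaction model is saturated in (a, s): per-stratum estimates must
  # equal an independent per-stratum refit exactly
  for (lev in 0:1) {
    sub <- df[df$s == lev, c("a", "y")]
    ref <- point_estimate(cohort_table(sub),
                          analysis_spec(outcome = "y", exposure = "a"))
    got <- pt$estimates[pt$estimates$group == paste0("s=", lev), ]
    expect_equal(got$estimate, ref$estimates$estimate, tolerance = 1e-7)
  }
})

test_that("numeric exposure contrast matches a raw-scale refit oracle", {
  set.seed(44)
  n <- 500
  df <- data.frame(x = rnorm(n, 40, 10), w = rbinom(n, 1, 0.4))
  df$y <- rbinom(n, 1, oracle_expit(-2 + 0.04 * df$x + 0.5 * df$w))
  sp <- analysis_spec(outcome = "y", exposure = "x", covariates = "w",
                      exposure_scalar = 10)
  pt <- point_estimate(cohort_table(df), sp)
  # independent route: untransformed glm, predictions at mean and mean + 10
  fit <- stats::glm(y ~ x + w, binomial(), df)
  m <- mean(df$x)
  p_lo <- mean(predict(fit, transform(df, x = m), type = "response"))
  p_hi <- mean(predict(fit, transform(df, x = m + 10), type = "response"))
  est <- setNames(pt$estimates$estimate, pt$estimates$measure)
  expect_equal(unname(est["risk_difference"]), p_hi - p_lo, tolerance = 1e-7)
  expect_equal(unname(est["risk_ratio"]), p_hi / p_lo, tolerance = 1e-7)
  # the report labels the raw contrast endpoints, not the coded 0/1 values
  ends <- as.numeric(sub("^x=", "",
                         strsplit(pt$estimates$contrast[1], " vs ")[[1]]))
  expect_equal(sort(ends), c(m, m + 10), tolerance = 1e-6)
  expect_identical(pt$centering, m)
})
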