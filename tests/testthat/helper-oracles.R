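# Independent oracles used across the suite. None of these touch glm() or
# any gmarginal internals: logistic fits go through a hand-coded likelihood
# (BFGS then Newton), standardization is explicit cell arithmetic, and
# percentiles are a hand-coded sort/interpolation rule.

oracle_expit <- function(x) 1 / (1 + exp(-x))

# ML logistic fit by optim on the hand-coded negative log-likelihood,
# polished with Newton steps on the analytic score/Hessian
oracle_logistic_fit <- function(X, y) {
  nll <- function(b) { eta <- X %*% b; sum(log(1 + exp(eta)) - y * eta) }
  grd <- function(b) {
    p <- 1 / (1 + exp(-X %*% b)); as.numeric(t(X) %*% (p - y))
  }
  b <- optim(rep(0, ncol(X)), nll, grd, method = "BFGS",
             control = list(reltol = 1e-16, maxit = 1000))$par
  for (i in 1:50) {
    p <- as.numeric(1 / (1 + exp(-X %*% b)))
    H <- t(X) %*% (X * (p * (1 - p)))
    step <- solve(H, as.numeric(t(X) %*% (p - y)))
    b <- b - step
    if (max(abs(step)) < 1e-14) break
  }
  b
}

# classical direct standardization by explicit cell counting:
# sum_w phat(Y | A = a, W = w) * Pr_hat(W = w)
oracle_direct_standardization <- function(a, w, y, a_level) {
  ws <- sort(unique(w))
  sum(vapply(ws, function(wl) {
    mean(y[a == a_level & w == wl]) * mean(w == wl)
  }, numeric(1)))
}

# textbook percentile with linear interpolation at h = (n - 1) p + 1
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# two-group 2x2 cohort: e1/n1 events among exposed, e0/n0 among unexposed
make_2x2_cohort <- function(e1, n1, e0, n0) {
  cohort_table(data.frame(
    a = rep(c(1, 0), c(n1, n0)),
    y = c(rep(c(1, 0), c(e1, n1 - e1)), rep(c(1, 0), c(e0, n0 - e0)))))
}

# two-group rate data: events and person-time per exposure group
make_rate_cohort <- function(e1, pt1, e0, pt0) {
  cohort_table(data.frame(a = c(1, 0), y = c(e1, e0), pt = c(pt1, pt0)),
               column_types = c(a = "binary01"))
}

# 8-row logistic fixture with every (A, W) cell mixed, so the MLE is finite
eight_row_fixture <- function() {
  data.frame(a = c(0, 0, 0, 0, 1, 1, 1, 1),
             w = c(0, 0, 1, 1, 0, 0, 1, 1),
             y = c(0, 1, 0, 1, 0, 1, 1, 1))
}

# fast default spec for the synthetic cohort
synth_spec <- function(...) {
  analysis_spec(outcome = "y", exposure = "exposed",
                covariates = c("age", "sex", "bmi", "smoke", "hyperten"),
                ...)
}
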