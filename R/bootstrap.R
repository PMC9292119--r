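#' Draw one bootstrap resample of a cohort
#'
#' Row mode draws `n_obs` rows with replacement. Cluster mode draws whole
#' clusters with replacement: each drawn cluster contributes all of its
#' member rows, so the resampled table may differ from the original in row
#' count. The caller controls the RNG state (the bootstrap seeds one
#' independent substream per replicate).
#'
#' @param table A `cohort_table`.
#' @param cluster_id Optional name of the cluster-identifier column.
#' @return A resampled `cohort_table`.
#' @export
resample_cohort <- function(table, cluster_id = NULL) {
  n <- nrow(table)
  if (is.null(cluster_id)) {
    if (n < 2L) stop("need at least 2 observations to resample", call. = FALSE)
    idx <- sample.int(n, n, replace = TRUE)
  } else {
    ids <- table[[cluster_id]]
    uniq <- unique(ids)
    if (length(uniq) < 2L) stop("need at least 2 clusters to resample",
                                call. = FALSE)
    rows_of <- split(seq_len(n), ids)
    drawn <- sample(as.character(uniq), length(uniq), replace = TRUE)
    idx <- unlist(rows_of[drawn], use.names = FALSE)
  }
  table[idx, , drop = FALSE]
}

#' G-computation with percentile-bootstrap confidence intervals
#'
#' The main entry point. Computes the g-computation point estimate on the
#' original data, then re-estimates it on `n_boot` bootstrap resamples
#' (rows, or whole clusters when `cluster_id` is set) and forms 95%
#' confidence intervals from the 2.5th and 97.5th percentiles of the
#' replicate estimates. Percentiles for ratio measures (risk ratio, odds
#' ratio, rate ratio) are taken on the natural-log scale and exponentiated.
#' The number needed to treat is reported without an interval: its
#' interval methods are not standardized and it is meant for
#' communication, not inference.
#'
#' A numeric exposure is centered once, on the original data, and that
#' centering value is reused in every replicate. Replicates whose model fit
#' fails (e.g. non-convergence in a sparse resample) are dropped and
#' counted in `n_boot_failed`; more than `spec$max_failure_frac` failures
#' aborts. One RNG substream is seeded per replicate from `spec$seed`, so
#' results are identical for any `parallel_workers` count.
#'
#' @param table A `cohort_table` (or data.frame coercible to one).
#' @param spec An [analysis_spec()].
#' @return A `gcomp_result`: `estimates` (data.frame with `group`,
#'   `contrast`, `measure`, `estimate`, `lower`, `upper`),
#'   `marginal_means`, `boot_draws` (successful-replicate estimates, one
#'   column per non-NNT measure), `n_boot_failed`, `centering_value`,
#'   `model`, and the validated `spec`.
#' @examples
#' gm <- generative_model(n = 300)
#' ct <- generate_cohort(gm, seed = 7)
#' spec <- analysis_spec(outcome = "y", exposure = "exposed",
#'                       covariates = c("age", "sex"), n_boot = 50, seed = 1)
#' res <- gcomp(ct, spec)
#' res$estimates
#' @export
gcomp <- function(table, spec) {
  v <- validate_spec(table, spec)
  table <- v$table; spec <- v$spec

  pt <- point_estimate(table, spec)
  center <- pt$centering
  keys <- names(estimate_vector(pt))

  set.seed(spec$seed)
  rep_seeds <- sample.int(2147483646L, spec$n_boot)

  one_rep <- function(r) {
    set.seed(rep_seeds[r])
    rs <- resample_cohort(table, spec$cluster_id)
    tryCatch(
      suppressWarnings(estimate_vector(
        point_estimate(rs, spec, centering_value = center))),
      error = function(e) NULL)
  }
  reps <- if (spec$parallel_workers > 1L)
    parallel::mclapply(seq_len(spec$n_boot), one_rep,
                       mc.cores = spec$parallel_workers)
  else lapply(seq_len(spec$n_boot), one_rep)

  ok <- !vapply(reps, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > spec$max_failure_frac * spec$n_boot)
    stop(n_failed, " of ", spec$n_boot, " bootstrap replicates failed ",
         "(ceiling ", format(spec$max_failure_frac * 100), "%); the model ",
         "is too fragile under resampling for percentile intervals",
         call. = FALSE)
  draws <- do.call(rbind, reps[ok])

  # NNT is excluded from the bootstrap draws: it carries no interval
  keep <- !endsWith(keys, "| nnt")
  draws <- draws[, keep, drop = FALSE]

  ci <- vapply(colnames(draws), function(k) {
    x <- draws[, k]
    x <- x[is.finite(x)]
    if (!length(x)) return(c(NA_real_, NA_real_))
    msr <- sub("^.* \\| ", "", k)
    if (msr %in% ratio_measures)
      exp(stats::quantile(log(x), c(0.025, 0.975), type = 7, names = FALSE))
    else
      stats::quantile(x, c(0.025, 0.975), type = 7, names = FALSE)
  }, numeric(2))

  est <- pt$estimates
  est$lower <- NA_real_; est$upper <- NA_real_
  for (j in seq_len(ncol(ci))) {
    i <- which(keys == colnames(ci)[j])
    est$lower[i] <- ci[1, j]; est$upper[i] <- ci[2, j]
  }

  structure(list(estimates = est, marginal_means = pt$marginal_means,
                 boot_draws = draws, n_boot_failed = n_failed,
                 centering_value = center, model = pt$model,
                 regime_labels = pt$regime_labels, spec = spec),
            class = "gcomp_result")
}

#' Bootstrap-distribution diagnostics
#'
#' Returns, per effect measure, the raw material for the standard
#' bootstrap-normality checks: histogram bins and quantile-quantile pairs
#' of the replicate estimates against a standard normal. Ratio measures are
#' transformed to the natural-log scale first, where their sampling
#' distributions are approximately symmetric. The Q-Q sample values are
#' standardized (centered at 0, unit variance), so points should follow the
#' identity line when the bootstrap distribution is normal.
#'
#' @param result A `gcomp_result` with at least 10 successful replicates.
#' @return A named list (one element per measure) of lists with fields
#'   `transform` ("identity" or "log"), `breaks`, `counts` (histogram) and
#'   `qq` (two-column matrix: theoretical, sample).
#' @export
diagnostics <- function(result) {
  stopifnot(inherits(result, "gcomp_result"))
  draws <- result$boot_draws
  if (is.null(draws) || nrow(draws) < 10L)
    stop("insufficient replicates for diagnostics (need >= 10)",
         call. = FALSE)
  out <- lapply(colnames(draws), function(k) {
    msr <- sub("^.* \\| ", "", k)
    x <- draws[, k]
    x <- x[is.finite(x)]
    trans <- if (msr %in% ratio_measures) "log" else "identity"
    if (trans == "log") x <- log(x)
    h <- graphics::hist(x, plot = FALSE)
    s <- sort((x - mean(x)) / stats::sd(x))
    list(transform = trans, breaks = h$breaks, counts = h$counts,
         qq = cbind(theoretical = stats::qnorm(stats::ppoints(length(s))),
                    sample = s))
  })
  names(out) <- colnames(draws)
  out
}

#' @export
print.gcomp_result <- function(x, ...) {
  cat("G-computation marginal effects (", x$spec$outcome_type,
      " outcome), 95% percentile bootstrap CI, R = ", x$spec$n_boot,
      if (x$n_boot_failed > 0)
        paste0(" (", x$n_boot_failed, " failed)"), "\n\n", sep = "")
  fe <- format_estimates(x$estimates)
  fe$`95% CI` <- ifelse(is.na(x$estimates$lower), "",
                        sprintf("(%.4g, %.4g)", x$estimates$lower,
                                x$estimates$upper))
  fe$lower <- NULL; fe$upper <- NULL
  print(fe, row.names = FALSE)
  cat("\nMarginal mean outcomes:\n")
  print(x$marginal_means, row.names = FALSE)
  if (!is.null(x$centering_value))
    cat("\nNumeric exposure centered at ", format(x$centering_value),
        "; contrast width ", format(x$spec$exposure_scalar), "\n", sep = "")
  invisible(x)
}

#' Plot bootstrap diagnostics
#'
#' Histogram and normal Q-Q plot of the bootstrap replicate estimates for
#' each effect measure (ratio measures on the natural-log scale).
#'
#' @param x A `gcomp_result`.
#' @param ... Unused.
#' @export
plot.gcomp_result <- function(x, ...) {
  d <- diagnostics(x)
  old <- graphics::par(mfrow = c(length(d), 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (k in names(d)) {
    msr <- sub("^.* \\| ", "", k)
    lab <- unname(measure_labels[msr])
    if (d[[k]]$transform == "log") lab <- paste0("log(", lab, ")")
    mids <- (utils::head(d[[k]]$breaks, -1) + utils::tail(d[[k]]$breaks, -1)) / 2
    graphics::plot(mids, d[[k]]$counts, type = "h", lwd = 6, lend = 1,
                   xlab = lab, ylab = "count", main = lab)
    graphics::plot(d[[k]]$qq[, 1], d[[k]]$qq[, 2],
                   xlab = "theoretical quantile", ylab = "standardized draw",
                   main = paste("Q-Q:", lab))
    graphics::abline(0, 1, lty = 2, col = "red")
  }
  invisible(x)
}
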