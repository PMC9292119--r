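#' Build the outcome-model design for a g-computation run
#'
#' Assembles the model frame and formula used by [fit_outcome_model()]:
#' the exposure enters as `.A` (a factor with the referent first, or a
#' centered/scaled numeric \eqn{(x - c)/s}), the subgroup as `.S` together
#' with the only permitted interaction `.A:.S`, and the person-time offset
#' as `offset(.off)` with `.off = log(offset column)`.
#'
#' @param table Validated `cohort_table` (from [validate_spec()]).
#' @param spec Validated `gcomp_spec`.
#' @param centering_value Optional number overriding the centering constant
#'   for a numeric exposure; used by the bootstrap so every resample shares
#'   the centering value of the original data.
#' @return A `gcomp_design` list: `formula`, `data` (model frame),
#'   `regimes` (exposure values to impose; referent first), `regime_labels`,
#'   `centering`, `scalar`, `has_offset`, `subgroup_levels`.
#' @export
build_design <- function(table, spec, centering_value = NULL) {
  stopifnot(isTRUE(spec$validated))
  md <- data.frame(.Y = as.numeric(table[[spec$outcome]]))

  ex <- table[[spec$exposure]]
  if (spec$exposure_type == "categorical") {
    if (nlevels(droplevels(ex)) < 2L)
      stop("exposure has a single level", call. = FALSE)
    md$.A <- ex
    regimes <- levels(ex)
    regime_labels <- paste0(spec$exposure, "=", regimes)
    centering <- NULL
    scalar <- 1
  } else {
    if (length(unique(ex)) < 2L)
      stop("exposure has a single level", call. = FALSE)
    centering <- if (!is.null(centering_value)) centering_value
      else if (isTRUE(spec$exposure_center)) mean(ex)
      else if (isFALSE(spec$exposure_center)) 0
      else as.numeric(spec$exposure_center)
    scalar <- spec$exposure_scalar
    md$.A <- (ex - centering) / scalar
    # contrast endpoints on the raw scale: center -> center + scalar
    regimes <- c(0, 1)
    regime_labels <- paste0(spec$exposure, "=",
                            format(c(centering, centering + scalar),
                                   trim = TRUE))
  }

  rhs <- ".A"
  # the subgroup enters once as .S, even if it is also listed in covariates
  covs <- setdiff(spec$covariates, spec$subgroup)
  if (!is.null(spec$subgroup)) {
    md$.S <- table[[spec$subgroup]]
    rhs <- c(rhs, ".S", ".A:.S")
  }
  for (z in covs) md[[z]] <- table[[z]]
  rhs <- c(rhs, covs)

  has_offset <- is_count_type(spec$outcome_type)
  if (has_offset) {
    md$.off <- if (is.null(spec$offset)) 0 else log(table[[spec$offset]])
    rhs <- c(rhs, "offset(.off)")
  }
  form <- stats::reformulate(rhs, response = ".Y")
  # a minimal environment: offset() must resolve, nothing else leaks in
  environment(form) <- new.env(parent = asNamespace("stats"))

  # refuse perfectly aliased designs up front
  mm <- stats::model.matrix(stats::as.formula(
    paste("~", paste(setdiff(rhs, "offset(.off)"), collapse = "+"))), md)
  if (qr(mm)$rank < ncol(mm))
    stop("model design is rank deficient (aliased columns)", call. = FALSE)

  structure(list(formula = form, data = md, regimes = regimes,
                 regime_labels = regime_labels, centering = centering,
                 scalar = scalar, has_offset = has_offset,
                 subgroup_levels = if (!is.null(spec$subgroup))
                   levels(md$.S)),
            class = "gcomp_design")
}

#' Fit the parametric outcome model
#'
#' Fits the generalized linear model matching the outcome type: binomial
#' with logit link (`binary`), Poisson with log link (`count`, `rate`),
#' negative binomial with log link and internally estimated dispersion theta
#' (`count_nb`, `rate_nb`; variance \eqn{\mu + \mu^2/\theta}), or gaussian
#' with identity link (`continuous`). Convergence uses a relative deviance
#' tolerance of 1e-8 within 100 iterations. Coefficients larger than 20 on
#' the link scale trigger a separation warning but not an error, since
#' bootstrap resamples of sparse strata may separate transiently.
#'
#' @param design A `gcomp_design` from [build_design()].
#' @param outcome_type Outcome family keyword (see [analysis_spec()]).
#' @return An `outcome_fit`: the underlying fit plus family/link metadata,
#'   `theta` (negative binomial only) and a `converged` flag.
#' @export
fit_outcome_model <- function(design, outcome_type) {
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  fam <- switch(outcome_type,
    binary = stats::binomial(link = "logit"),
    count = , rate = stats::poisson(link = "log"),
    continuous = stats::gaussian(link = "identity"),
    count_nb = , rate_nb = NULL)

  if (is_nb_type(outcome_type)) {
    fit <- MASS::glm.nb(design$formula, data = design$data, control = ctrl)
    theta <- fit$theta
    family_name <- "negative binomial"
    link <- "log"
  } else {
    fit <- stats::glm(design$formula, data = design$data, family = fam,
                      control = ctrl)
    theta <- NULL
    family_name <- fam$family
    link <- fam$link
  }
  if (!isTRUE(fit$converged))
    stop("outcome model did not converge in 100 IRLS iterations",
         call. = FALSE)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("model design is rank deficient (aliased columns)", call. = FALSE)
  if (any(abs(cf) > 20))
    warning("possible separation: |coefficient| > 20 on the link scale",
            call. = FALSE)

  structure(list(fit = fit, family = family_name, link = link,
                 coefficients = cf, theta = theta,
                 converged = fit$converged, design = design,
                 outcome_type = outcome_type),
            class = "outcome_fit")
}

#' Predict mean outcomes on the response scale
#'
#' Evaluates the fitted model's inverse-link at the linear predictor for
#' each supplied row. For models with a person-time offset,
#' `offset_override` replaces the per-row person-time, which is how
#' counterfactual rates are put on the reporting denominator (the rate
#' multiplier).
#'
#' @param model An `outcome_fit`.
#' @param newdata Rows carrying every design column (`.A`, covariates, `.S`
#'   when subgrouped).
#' @param offset_override Optional positive number: person-time at which to
#'   predict (rate/count models only).
#' @return Numeric vector of predicted mean outcomes.
#' @export
predict_response <- function(model, newdata, offset_override = NULL) {
  needed <- setdiff(all.vars(model$design$formula), ".Y")
  missing_cols <- setdiff(needed, names(newdata))
  if (length(missing_cols))
    stop("rows are missing design column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!is.null(offset_override)) {
    if (!model$design$has_offset)
      stop("offset_override given but model has no offset", call. = FALSE)
    stopifnot(offset_override > 0)
    newdata$.off <- log(offset_override)
  }
  as.numeric(stats::predict(model$fit, newdata = newdata, type = "response"))
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat("<outcome_fit> ", x$family, " family, ", x$link, " link\n", sep = "")
  if (!is.null(x$theta)) cat("  dispersion theta = ",
                             format(x$theta), "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}
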