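#' Describe one g-computation analysis
#'
#' An `analysis_spec` records the role of every column and all tuning
#' parameters for a single g-computation run: which column is the outcome,
#' which the exposure, which covariates enter the outcome model, the outcome
#' family, and the bootstrap settings. Either `formula` or the
#' `outcome`/`exposure` pair must be given, never both.
#'
#' @param outcome Name of the outcome column.
#' @param exposure Name of the exposure column (binary/categorical factor or
#'   numeric). Categorical exposures use their first level as the referent.
#' @param covariates Character vector of covariate column names (optional).
#' @param formula Alternative to `outcome`/`exposure`/`covariates`: an
#'   additive model formula `y ~ x + z1 + z2` whose first right-hand-side
#'   term is the exposure. Interaction syntax (`*`, `:`) is rejected;
#'   subgroup analysis adds the only supported interaction internally.
#' @param outcome_type One of `"binary"` (binomial/logit), `"count"` or
#'   `"rate"` (Poisson/log), `"count_nb"` or `"rate_nb"` (negative
#'   binomial/log with dispersion estimated internally), `"continuous"`
#'   (gaussian/identity).
#' @param subgroup Optional column defining strata for effect-measure
#'   modification; coerced to a factor, and an exposure-by-subgroup
#'   interaction is added to the model.
#' @param offset Optional person-time column (count/rate outcomes only);
#'   strictly positive, on the linear scale — its natural log enters the
#'   model. Required for `rate`/`rate_nb`.
#' @param rate_multiplier Person-time denominator used when predicting
#'   counterfactual rates (count/rate outcomes only), in the units of the
#'   offset column. E.g. an offset in days with `rate_multiplier =
#'   365.25 * 100` reports rates per 100 person-years. Default 1.
#' @param exposure_scalar Contrast width for a numeric exposure: effects are
#'   reported for an increase of this many raw units. Default 1.
#' @param exposure_center For a numeric exposure: `TRUE` to center at the
#'   sample mean, a number to center at that value (use this to share one
#'   centering value across bootstrap resamples), or `FALSE` for no
#'   centering. Default `TRUE`.
#' @param n_boot Number of bootstrap resamples (R). Default 200; 1000 is
#'   recommended for final analyses.
#' @param cluster_id Optional column of cluster identifiers; when set, the
#'   bootstrap resamples whole clusters instead of rows.
#' @param seed Integer seed driving all bootstrap randomness.
#' @param parallel_workers Number of worker processes for the bootstrap.
#'   Results are identical for any worker count at a given seed.
#' @param drop_missing If `TRUE`, rows with missing values in referenced
#'   columns are dropped with a message; the default is to fail with a
#'   count of the offending rows.
#' @param max_failure_frac Abort if more than this fraction of bootstrap
#'   replicates fail to fit. Default 0.1.
#' @return An object of class `gcomp_spec`.
#' @export
analysis_spec <- function(outcome = NULL, exposure = NULL, covariates = NULL,
                          formula = NULL,
                          outcome_type = c("binary", "count", "count_nb",
                                           "rate", "rate_nb", "continuous"),
                          subgroup = NULL, offset = NULL,
                          rate_multiplier = 1,
                          exposure_scalar = 1, exposure_center = TRUE,
                          n_boot = 200, cluster_id = NULL, seed = 1L,
                          parallel_workers = 1L, drop_missing = FALSE,
                          max_failure_frac = 0.1) {
  outcome_type <- match.arg(outcome_type)
  has_formula <- !is.null(formula)
  has_names <- !is.null(outcome) || !is.null(exposure)
  if (has_formula && has_names)
    stop("provide either `formula` or `outcome`+`exposure`, not both",
         call. = FALSE)
  if (!has_formula && (is.null(outcome) || is.null(exposure)))
    stop("provide either `formula` or both `outcome` and `exposure`",
         call. = FALSE)
  if (has_formula) {
    parsed <- parse_model_formula(formula)
    outcome <- parsed$outcome
    exposure <- parsed$exposure
    covariates <- parsed$covariates
  }
  rate_multiplier <- as.numeric(rate_multiplier)
  if (!is_count_type(outcome_type)) {
    if (!is.null(offset))
      stop("`offset` is only legal for count/rate outcomes", call. = FALSE)
    if (rate_multiplier != 1)
      stop("`rate_multiplier` is only legal for count/rate outcomes",
           call. = FALSE)
  }
  if (outcome_type %in% c("rate", "rate_nb") && is.null(offset))
    stop("offset required for rate outcomes", call. = FALSE)
  stopifnot(is.numeric(rate_multiplier), length(rate_multiplier) == 1L,
            rate_multiplier > 0)
  stopifnot(is.numeric(exposure_scalar), length(exposure_scalar) == 1L,
            exposure_scalar > 0)
  if (!(isTRUE(exposure_center) || isFALSE(exposure_center) ||
        (is.numeric(exposure_center) && length(exposure_center) == 1L)))
    stop("`exposure_center` must be TRUE, FALSE or a number", call. = FALSE)
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 1L) stop("n_boot must be >= 1", call. = FALSE)
  stopifnot(max_failure_frac >= 0, max_failure_frac <= 1)

  structure(list(
    outcome = outcome, exposure = exposure,
    covariates = as.character(covariates %||% character()),
    outcome_type = outcome_type,
    subgroup = subgroup, offset = offset,
    rate_multiplier = rate_multiplier,
    exposure_scalar = exposure_scalar, exposure_center = exposure_center,
    n_boot = n_boot, cluster_id = cluster_id,
    seed = as.integer(seed), parallel_workers = as.integer(parallel_workers),
    drop_missing = isTRUE(drop_missing),
    max_failure_frac = max_failure_frac,
    exposure_type = NULL, validated = FALSE
  ), class = "gcomp_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count_type <- function(tt) tt %in% c("count", "count_nb", "rate", "rate_nb")
is_nb_type <- function(tt) tt %in% c("count_nb", "rate_nb")

# Additive Wilkinson formula -> roles. First RHS term is the exposure.
parse_model_formula <- function(formula) {
  f <- stats::as.formula(formula)
  if (length(f) != 3L) stop("formula must have an outcome (left side)",
                            call. = FALSE)
  rhs_txt <- paste(deparse(f[[3]]), collapse = "")
  if (grepl("[*:]", rhs_txt))
    stop("interaction terms are not allowed in the model formula; ",
         "use `subgroup` for stratified effects", call. = FALSE)
  terms_obj <- stats::terms(f)
  labs <- attr(terms_obj, "term.labels")
  if (length(labs) < 1L) stop("formula needs at least an exposure term",
                              call. = FALSE)
  if (!all(grepl("^[.A-Za-z][.A-Za-z0-9_]*$", labs)))
    stop("formula terms must be plain column names", call. = FALSE)
  list(outcome = all.vars(f[[2]]), exposure = labs[1],
       covariates = labs[-1])
}

#' Validate an analysis against a cohort table
#'
#' Checks that every referenced column exists and is usable, resolves the
#' exposure as categorical (referent = first level) or numeric, coerces the
#' subgroup to a factor, coerces a two-level outcome to 0/1 for binary
#' analyses, and rejects (or, with `drop_missing`, drops and counts) rows
#' with missing values in referenced columns. Validation is idempotent:
#' re-validating a validated pair changes nothing.
#'
#' @param table A [cohort_table()].
#' @param spec An [analysis_spec()].
#' @return A list with elements `table` (normalized `cohort_table`) and
#'   `spec` (validated `gcomp_spec` with `exposure_type` filled in).
#' @export
validate_spec <- function(table, spec) {
  stopifnot(inherits(spec, "gcomp_spec"))
  if (!inherits(table, "cohort_table")) {
    # raw data.frame: free-text exposure is refused, not silently factored
    if (is.data.frame(table) && spec$exposure %in% names(table) &&
        is.character(table[[spec$exposure]]))
      stop("character exposure variables are not accepted; supply a factor ",
           "or numeric column", call. = FALSE)
    table <- cohort_table(table)
  }
  ty <- column_types(table)

  used <- unique(c(spec$outcome, spec$exposure, spec$covariates,
                   spec$subgroup, spec$offset, spec$cluster_id))
  unknown <- setdiff(used, names(table))
  if (length(unknown))
    stop("unknown column name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  # missing-value policy: fail with a count, or drop loudly on request
  miss <- rowSums(is.na(table[, used, drop = FALSE])) > 0
  if (any(miss)) {
    if (spec$drop_missing) {
      message(sum(miss), " row(s) with missing values dropped")
      table <- table[!miss, , drop = FALSE]
      if (nrow(table) == 0L) stop("no rows left after dropping missing values",
                                  call. = FALSE)
    } else {
      stop(sum(miss), " row(s) have missing values in referenced columns; ",
           "use drop_missing = TRUE to drop them", call. = FALSE)
    }
  }

  # exposure: categorical (factor / binary01) or numeric; never free text
  ex <- table[[spec$exposure]]
  if (ty[[spec$exposure]] == "categorical") {
    spec$exposure_type <- "categorical"
  } else if (ty[[spec$exposure]] == "binary01") {
    table[[spec$exposure]] <- factor(ex, levels = c(0, 1))
    attr(table, "col_types")[[spec$exposure]] <- "categorical"
    spec$exposure_type <- "categorical"
  } else if (is.numeric(ex)) {
    spec$exposure_type <- "numeric"
  } else {
    stop("character exposure variables are not accepted; supply a factor ",
         "or numeric column", call. = FALSE)
  }
  if (spec$exposure_type == "categorical") {
    if (spec$exposure_scalar != 1 || !isTRUE(spec$exposure_center))
      stop("exposure_scalar/exposure_center only apply to a numeric exposure",
           call. = FALSE)
    table[[spec$exposure]] <- droplevels(table[[spec$exposure]])
    if (nlevels(table[[spec$exposure]]) < 2L)
      stop("exposure has a single level", call. = FALSE)
  }

  # covariates must not be free text either
  for (z in spec$covariates) {
    if (!ty[[z]] %in% c("categorical", "binary01", "numeric"))
      stop("covariate '", z, "' has unusable type", call. = FALSE)
  }

  # subgroup -> factor
  if (!is.null(spec$subgroup) &&
      attr(table, "col_types")[[spec$subgroup]] != "categorical") {
    table[[spec$subgroup]] <- as_ordered_factor(table[[spec$subgroup]])
    attr(table, "col_types")[[spec$subgroup]] <- "categorical"
  }
  if (!is.null(spec$subgroup)) {
    tab <- base::table(table[[spec$subgroup]])
    if (any(tab < 2L)) stop("subgroup level with fewer than 2 rows",
                            call. = FALSE)
  }

  # offset strictly positive
  if (!is.null(spec$offset)) {
    off <- table[[spec$offset]]
    if (!is.numeric(off) || any(off <= 0))
      stop("offset column must be strictly positive numeric", call. = FALSE)
  }

  # binary outcome must be codeable as 0/1 (first factor level -> 0)
  y <- table[[spec$outcome]]
  if (spec$outcome_type == "binary") {
    if (is.factor(y)) {
      if (nlevels(y) != 2L)
        stop("binary outcome must have exactly 2 levels", call. = FALSE)
      table[[spec$outcome]] <- as.numeric(y) - 1
      attr(table, "col_types")[[spec$outcome]] <- "binary01"
    } else if (!all(y %in% c(0, 1))) {
      stop("binary outcome must be coded 0/1", call. = FALSE)
    }
  } else {
    if (!is.numeric(y))
      stop("outcome must be numeric for outcome_type '", spec$outcome_type,
           "'", call. = FALSE)
    if (is_count_type(spec$outcome_type) && any(y < 0))
      stop("count/rate outcome must be non-negative", call. = FALSE)
  }

  spec$validated <- TRUE
  list(table = table, spec = spec)
}

#' @export
print.gcomp_spec <- function(x, ...) {
  cat("<gcomp_spec> ", x$outcome_type, " outcome\n", sep = "")
  cat("  outcome:   ", x$outcome, "\n  exposure:  ", x$exposure, "\n", sep = "")
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  if (!is.null(x$subgroup)) cat("  subgroup:  ", x$subgroup, "\n", sep = "")
  if (!is.null(x$offset))
    cat("  offset:    ", x$offset, " (rate multiplier ", x$rate_multiplier,
        ")\n", sep = "")
  cat("  bootstrap: R = ", x$n_boot,
      if (!is.null(x$cluster_id)) paste0(", cluster = ", x$cluster_id),
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
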