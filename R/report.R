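#' Write a g-computation result to disk
#'
#' `"tabular"` writes a CSV with one row per (measure, contrast, subgroup)
#' and columns `estimate`, `lower`, `upper`; the number-needed-to-treat row
#' has empty interval cells. `"report"` writes a JSON document that
#' additionally echoes the analysis spec, seed, failed-replicate count,
#' centering value and percentile convention, at full double precision so
#' a written report re-read with [read_result()] reproduces every point
#' estimate exactly.
#'
#' @param result A `gcomp_result` (or, for `"tabular"`, a `gcomp_point`).
#' @param path Output file path.
#' @param format `"tabular"` or `"report"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = c("tabular", "report")) {
  format <- match.arg(format)
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("unwritable path: ", dirname(path), call. = FALSE)

  if (format == "tabular") {
    est <- format_estimates(result$estimates)
    if (is.null(est$lower)) { est$lower <- NA_real_; est$upper <- NA_real_ }
    utils::write.csv(est, path, row.names = FALSE, na = "")
    return(invisible(path))
  }

  stopifnot(inherits(result, "gcomp_result"))
  spec <- result$spec
  doc <- list(
    spec = spec[c("outcome", "exposure", "covariates", "outcome_type",
                  "subgroup", "offset", "rate_multiplier", "exposure_scalar",
                  "exposure_center", "n_boot", "cluster_id", "seed",
                  "parallel_workers")],
    n_boot_failed = result$n_boot_failed,
    centering_value = result$centering_value,
    percentile_rule = "linear interpolation of order statistics (type 7)",
    estimates = result$estimates,
    marginal_means = result$marginal_means)
  # 17 significant digits: doubles survive the round trip exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", dataframe = "columns")
  invisible(path)
}

#' Read back a structured JSON report
#'
#' @param path Path written by [write_result()] with `format = "report"`.
#' @return A list with `spec` fields, `estimates` and `marginal_means`
#'   data.frames, `n_boot_failed` and `centering_value`.
#' @export
read_result <- function(path) {
  doc <- jsonlite::fromJSON(path)
  doc$estimates <- as.data.frame(doc$estimates)
  doc$marginal_means <- as.data.frame(doc$marginal_means)
  doc
}
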