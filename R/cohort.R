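#' Construct a validated cohort table
#'
#' A `cohort_table` is a plain `data.frame` carrying an explicit type for
#' every column: `"binary01"` (numeric coded 0/1), `"categorical"` (a factor
#' whose first level is the referent for modelling) or `"numeric"`. All
#' analysis functions in this package consume a `cohort_table`; building one
#' up front makes referent levels and variable coding explicit instead of
#' relying on whatever a CSV reader inferred.
#'
#' @param data A `data.frame` of observations, one row per unit.
#' @param column_types Optional named character vector mapping column names
#'   to `"binary01"`, `"categorical"` or `"numeric"`. Columns not named here
#'   are typed by inference: character/factor columns become categorical
#'   (levels sorted ascending unless the column was already a factor with an
#'   explicit level order), numeric columns whose non-missing values are all
#'   0 or 1 become `binary01`, and all other numeric columns stay numeric.
#' @return A `cohort_table` (a `data.frame` with a `col_types` attribute).
#' @examples
#' ct <- cohort_table(data.frame(y = c(0, 1, 1), x = c("a", "b", "a")))
#' column_types(ct)
#' @export
cohort_table <- function(data, column_types = NULL) {
  if (!is.data.frame(data)) stop("`data` must be a data.frame", call. = FALSE)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  nms <- names(data)
  if (anyDuplicated(nms)) {
    stop("duplicate column names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0L) stop("empty table: no data rows", call. = FALSE)
  if (!is.null(column_types)) {
    bad <- setdiff(names(column_types), nms)
    if (length(bad)) stop("column_types names unknown column(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    ok <- column_types %in% c("binary01", "categorical", "numeric")
    if (!all(ok)) stop("unknown column type(s): ",
                       paste(unique(column_types[!ok]), collapse = ", "),
                       call. = FALSE)
  }

  types <- character(length(nms))
  names(types) <- nms
  for (nm in nms) {
    forced <- if (!is.null(column_types) && nm %in% names(column_types))
      column_types[[nm]] else NA_character_
    col <- data[[nm]]
    if (!is.na(forced)) {
      data[[nm]] <- switch(forced,
        categorical = as_ordered_factor(col),
        binary01    = as_binary01(col, nm),
        numeric     = {
          if (is.factor(col)) col <- as.character(col)
          v <- suppressWarnings(as.numeric(col))
          if (anyNA(v) && !anyNA(col))
            stop("column '", nm, "' cannot be coerced to numeric", call. = FALSE)
          v
        })
      types[[nm]] <- forced
    } else if (is.factor(col)) {
      types[[nm]] <- "categorical"
    } else if (is.character(col) || is.logical(col)) {
      if (is.logical(col)) {
        data[[nm]] <- as.numeric(col)
        types[[nm]] <- "binary01"
      } else {
        data[[nm]] <- as_ordered_factor(col)
        types[[nm]] <- "categorical"
      }
    } else if (is.numeric(col)) {
      vals <- unique(col[!is.na(col)])
      types[[nm]] <- if (length(vals) && all(vals %in% c(0, 1)))
        "binary01" else "numeric"
    } else {
      stop("column '", nm, "' has unsupported type ", class(col)[1],
           call. = FALSE)
    }
  }
  structure(data, col_types = types, class = c("cohort_table", "data.frame"))
}

# ascending sort of raw values defines the level order; first level = referent
as_ordered_factor <- function(x) {
  if (is.factor(x)) return(x)
  lev <- sort(unique(as.character(x[!is.na(x)])))
  # numeric-looking labels sort numerically so "10" follows "2"
  num <- suppressWarnings(as.numeric(lev))
  if (!anyNA(num)) lev <- lev[order(num)]
  factor(as.character(x), levels = lev)
}

as_binary01 <- function(x, nm) {
  if (is.factor(x)) {
    if (nlevels(x) != 2L)
      stop("column '", nm, "' must have exactly 2 levels for binary01",
           call. = FALSE)
    return(as.numeric(x) - 1)  # first level -> 0
  }
  v <- suppressWarnings(as.numeric(as.character(x)))
  if (!all(v[!is.na(v)] %in% c(0, 1)))
    stop("column '", nm, "' is not coded 0/1", call. = FALSE)
  v
}

#' Read a cohort table from CSV
#'
#' Reads an RFC-4180 CSV file with a header row and applies the
#' [cohort_table()] typing rules.
#'
#' @param path Path to a CSV file.
#' @param column_types Optional named character vector as in [cohort_table()].
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path, column_types = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cohort_table(df, column_types = column_types)
}

#' Column types of a cohort table
#' @param x A `cohort_table`.
#' @return Named character vector of column types.
#' @export
column_types <- function(x) attr(x, "col_types")

#' @export
print.cohort_table <- function(x, ...) {
  ty <- column_types(x)
  cat("<cohort_table> ", nrow(x), " observations, ", ncol(x), " columns\n",
      sep = "")
  for (nm in names(ty)) {
    extra <- if (ty[[nm]] == "categorical")
      paste0(" [referent ", levels(x[[nm]])[1], "]") else ""
    cat("  ", format(nm, width = 14), ty[[nm]], extra, "\n", sep = "")
  }
  invisible(x)
}

# subsetting keeps the class and type metadata (used by bootstrap resampling)
#' @export
`[.cohort_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    ty <- attr(x, "col_types")
    attr(out, "col_types") <- ty[names(out)]
    class(out) <- c("cohort_table", "data.frame")
  }
  out
}
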