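DRYING_COLUMNS <- c("sample_id", "pretreatment_min", "temperature_C",
                    "time_min")

#' Validate a long-format drying dataset
#'
#' Checks the schema used throughout the package: one row per
#' (pretreatment, temperature, time) with either a `moisture_ratio` column or
#' a `weight_g` column. Weights are converted to moisture ratios per cell
#' using the final (equilibrium) weight as the dry-matter anchor:
#' `MR = (W_t - W_end) / (W_0 - W_end)`.
#'
#' @param data Data frame to validate.
#' @return The validated data frame, with `moisture_ratio` guaranteed.
#' @export
validate_drying_data <- function(data) {
  if (!is.data.frame(data)) stop("drying data must be a data frame",
                                 call. = FALSE)
  missing_cols <- setdiff(setdiff(DRYING_COLUMNS, "sample_id"), names(data))
  if (length(missing_cols) > 0) {
    stop("drying data lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"moisture_ratio" %in% names(data)) {
    if (!"weight_g" %in% names(data)) {
      stop("drying data needs a moisture_ratio or weight_g column",
           call. = FALSE)
    }
    parts <- split(data, data[, c("pretreatment_min", "temperature_C")],
                   drop = TRUE)
    parts <- lapply(parts, function(d) {
      d <- d[order(d$time_min), ]
      w_end <- min(d$weight_g)
      w0 <- d$weight_g[d$time_min == min(d$time_min)][1]
      if (w0 <= w_end) stop("degenerate weight series: no mass loss",
                            call. = FALSE)
      d$moisture_ratio <- (d$weight_g - w_end) / (w0 - w_end)
      d
    })
    data <- do.call(rbind, c(parts, make.row.names = FALSE))
  }
  num <- c("pretreatment_min", "temperature_C", "time_min", "moisture_ratio")
  for (cn in num) {
    if (!is.numeric(data[[cn]])) {
      stop("column ", cn, " must be numeric", call. = FALSE)
    }
  }
  data
}

#' Read a long-format drying dataset from CSV
#'
#' @param path CSV file with header: `sample_id`, `pretreatment_min`,
#'   `temperature_C`, `time_min` and `moisture_ratio` (or `weight_g`).
#' @return Validated data frame (see [validate_drying_data()]).
#' @export
read_drying_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_drying_data(data)
}

#' Write a data frame to CSV with stable float formatting
#'
#' Numeric columns are written with 10 significant digits so write-read
#' round-trips are value-identical at that precision.
#'
#' @param data Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(data, path) {
  out <- data
  for (cn in names(out)) {
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]])) {
      out[[cn]] <- sprintf("%.10g", out[[cn]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Table-style descriptive statistics
#'
#' Per-column summary in the spreadsheet convention: mean, standard error of
#' the mean, median, mode (most frequent value; smallest on ties), standard
#' deviation, sample variance, excess kurtosis and skewness
#' (bias-corrected sample formulas), range, minimum, maximum, sum and count.
#' Skewness and kurtosis are NA for constant columns or fewer than 3 (4)
#' observations.
#'
#' @param data Data frame; non-numeric columns are ignored.
#' @param columns Optional character vector restricting the summary.
#' @return Data frame with one row per statistic and one column per variable.
#' @export
describe_drying <- function(data, columns = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(columns)) {
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  if (length(columns) == 0) stop("no numeric columns to describe",
                                 call. = FALSE)
  stat_names <- c("Mean", "Standard Error", "Median", "Mode",
                  "Standard Deviation", "Sample Variance", "Kurtosis",
                  "Skewness", "Range", "Minimum", "Maximum", "Sum", "Count")
  out <- data.frame(statistic = stat_names)
  for (cn in columns) {
    x <- data[[cn]]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0) {
      out[[cn]] <- NA_real_
      next
    }
    tab <- table(x)
    mode_val <- as.numeric(names(tab)[tab == max(tab)])[1]
    s <- stats::sd(x)
    skew <- if (n >= 3 && s > 0) {
      n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
    } else NA_real_
    kurt <- if (n >= 4 && s > 0) {
      n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) *
        sum(((x - mean(x)) / s)^4) - 3 * (n - 1)^2 / ((n - 2) * (n - 3))
    } else NA_real_
    out[[cn]] <- c(mean(x), s / sqrt(n), stats::median(x), mode_val,
                   s, s^2, kurt, skew, diff(range(x)), min(x), max(x),
                   sum(x), n)
  }
  out
}
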