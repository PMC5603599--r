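#' Construct a uniform 1-Hz physiological series
#'
#' The package's basic container: one sample per second, a value column and
#' an artifact mask. Vigilance series (`label = "V"`) hold ordinal stage
#' scores 1-7 (7 = active wakefulness, 1 = sleep onset), heart rate is in
#' beats per minute, skin conductance level in microsiemens.
#'
#' @param values Numeric vector of samples, one per second.
#' @param mask Logical vector, `TRUE` where the sample is an artifact or
#'   missing. Recycled from a single value. `NA` values are masked
#'   automatically.
#' @param label Signal label, one of `"V"`, `"HR"`, `"SCL"` (free-form
#'   labels are allowed for derived signals).
#' @param t0 Time of the first sample in seconds.
#'
#' @return A tibble of class `uniform_series` with columns `time_s`,
#'   `value`, `mask` and attributes `label` and `dt` (always 1 s).
#' @export
#' @examples
#' uniform_series(c(60, 61, NA, 62), label = "HR")
uniform_series <- function(values, mask = FALSE, label = "V", t0 = 0) {
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0L) abort("`values` must be non-empty.")
  mask <- rep_len(as.logical(mask), n)
  mask <- mask | is.na(values)
  if (length(mask) != n) abort("`values` and `mask` must have equal length.")
  out <- tibble(
    time_s = t0 + seq_len(n) - 1,
    value = values,
    mask = mask
  )
  new_uniform_series(out, label = label)
}

new_uniform_series <- function(x, label = "V") {
  structure(
    x,
    label = label,
    dt = 1,
    class = c("uniform_series", class(tibble()))
  )
}

#' Test for / validate a uniform series
#'
#' @param x Object to test.
#' @return `is_uniform_series()` returns a logical scalar;
#'   `validate_uniform_series()` returns `x` invisibly or raises a
#'   descriptive error.
#' @export
is_uniform_series <- function(x) inherits(x, "uniform_series")

#' @rdname is_uniform_series
#' @export
validate_uniform_series <- function(x) {
  if (!is.data.frame(x)) abort("A uniform series must be a data frame.")
  need <- c("time_s", "value", "mask")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("Series is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(x) > 1 && any(diff(x$time_s) != 1)) {
    abort("Series `time_s` must increase in steps of exactly 1 s.")
  }
  if (length(x$value) != length(x$mask)) {
    abort("`value` and `mask` must have equal length.")
  }
  invisible(x)
}

series_label <- function(x) attr(x, "label") %||% "signal"

# Keep the class and attributes through dplyr-style subsetting used internally.
reseries <- function(new_df, template) {
  new_uniform_series(as_tibble(new_df), label = series_label(template))
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf(
    "# uniform_series <%s>: %d s, %d masked (%.1f%%)\n",
    series_label(x), nrow(x), sum(x$mask), 100 * mean(x$mask)
  ))
  NextMethod()
}
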