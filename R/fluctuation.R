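#' Normalised tent (triangular) smoothing kernel
#'
#' Discrete triangular weights `w_k = 1 - |k - c| / (c + 1)` with
#' `c = (n - 1) / 2`, normalised to unit sum. The length `n` is
#' `round(width_s / dt)` forced odd (rounded up) so the filter is
#' zero-phase: smoothing never shifts peak times, which matters for the
#' period and latency measures downstream. Endpoint weights are positive.
#'
#' @param width_s Kernel width n_f in seconds (>= 3 * `dt`).
#' @param dt Sample interval in seconds.
#' @return An object of class `tent_kernel`: list with `width_s`, `dt`
#'   and unit-sum `weights`.
#' @export
#' @examples
#' tent_kernel(3)$weights  # 0.25 0.50 0.25
tent_kernel <- function(width_s, dt = 1) {
  if (width_s < 3 * dt) abort("Tent width must be at least 3 samples.")
  n <- round(width_s / dt)
  if (n %% 2 == 0) n <- n + 1
  c0 <- (n - 1) / 2
  w <- 1 - abs(seq_len(n) - 1 - c0) / (c0 + 1)
  structure(
    list(width_s = width_s, dt = dt, weights = w / sum(w)),
    class = "tent_kernel"
  )
}

#' Smooth a series with a tent kernel
#'
#' Same-length convolution with reflected-boundary padding (the signal is
#' mirrored about its end samples, without repeating them). Reflection
#' preserves constants exactly and avoids the edge attenuation that
#' zero-padding would introduce, which would otherwise create spurious
#' boundary extrema in the cycle detection.
#'
#' @param series A gap-free `uniform_series` or numeric vector.
#' @param kernel A `tent_kernel` (or a numeric width, converted with
#'   [tent_kernel()]).
#' @return Numeric vector, same length as the input.
#' @export
filter_tent <- function(series, kernel) {
  x <- if (is.data.frame(series)) series$value else as.numeric(series)
  if (is.numeric(kernel)) kernel <- tent_kernel(kernel)
  w <- kernel$weights
  h <- (length(w) - 1) / 2
  n <- length(x)
  if (n < h + 2) abort("Series shorter than half the kernel; cannot filter.")
  left <- x[(h + 1):2]
  right <- x[(n - 1):(n - h)]
  padded <- c(left, x, right)
  sm <- stats::filter(padded, w, method = "convolution", sides = 2)
  as.numeric(sm[(h + 1):(h + n)])
}

#' Locate alternating local maxima and minima
#'
#' Detects strict local extrema; plateaus (runs of equal values) collapse
#' to their centre sample. The output is forced to alternate: when two
#' maxima occur without an intervening minimum the lower one is dropped
#' (symmetrically the higher of two adjacent minima). End samples are
#' never extrema.
#'
#' @param filtered Numeric vector (typically from [filter_tent()]).
#' @return List with integer vectors `maxima_idx` and `minima_idx`
#'   (1-based sample indices). Both empty for monotone/constant input.
#' @export
find_cycles <- function(filtered) {
  x <- as.numeric(filtered)
  if (length(x) < 3) abort("Need at least 3 samples to find cycles.")
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) {
    return(list(maxima_idx = integer(0), minima_idx = integer(0)))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  centers <- starts + (r$lengths - 1L) %/% 2L
  v <- r$values
  i <- 2:(k - 1)
  is_max <- v[i] > v[i - 1] & v[i] > v[i + 1]
  is_min <- v[i] < v[i - 1] & v[i] < v[i + 1]
  idx <- centers[i]
  ext_idx <- idx[is_max | is_min]
  ext_type <- ifelse(is_max[is_max | is_min], 1L, -1L)  # 1 = max
  o <- order(ext_idx)
  ext_idx <- ext_idx[o]
  ext_type <- ext_type[o]

  # enforce alternation with a stack: among same-type neighbours keep the
  # more extreme one
  keep_idx <- integer(0)
  keep_type <- integer(0)
  for (j in seq_along(ext_idx)) {
    if (length(keep_idx) > 0 && keep_type[length(keep_type)] == ext_type[j]) {
      last <- length(keep_idx)
      better <-
        (ext_type[j] == 1L && x[ext_idx[j]] > x[keep_idx[last]]) ||
        (ext_type[j] == -1L && x[ext_idx[j]] < x[keep_idx[last]])
      if (better) keep_idx[last] <- ext_idx[j]
    } else {
      keep_idx <- c(keep_idx, ext_idx[j])
      keep_type <- c(keep_type, ext_type[j])
    }
  }
  list(
    maxima_idx = keep_idx[keep_type == 1L],
    minima_idx = keep_idx[keep_type == -1L]
  )
}

#' Cycle amplitudes around each maximum
#'
#' For every maximum flanked by a preceding and a following minimum the
#' cycle amplitude is the mean of the two rises:
#' `((max - prev_min) + (max - next_min)) / 2`. Boundary maxima that lack
#' a flanking minimum carry no amplitude and are excluded from the cycle
#' set.
#'
#' @param filtered Numeric vector the extrema were found in.
#' @param maxima_idx,minima_idx Alternating extrema from [find_cycles()].
#' @return Tibble with columns `max_idx` and `amplitude`, one row per
#'   interior maximum.
#' @export
cycle_amplitudes <- function(filtered, maxima_idx, minima_idx) {
  x <- as.numeric(filtered)
  keep <- vapply(maxima_idx, function(i) {
    any(minima_idx < i) && any(minima_idx > i)
  }, logical(1))
  mx <- maxima_idx[keep]
  amp <- vapply(mx, function(i) {
    prev <- max(minima_idx[minima_idx < i])
    nxt <- min(minima_idx[minima_idx > i])
    ((x[i] - x[prev]) + (x[i] - x[nxt])) / 2
  }, numeric(1))
  tibble(max_idx = as.integer(mx), amplitude = amp)
}

#' Fluctuation period of a signal at a given tent-filter width
#'
#' The full period estimator: smooth with a tent kernel of width
#' `width_s`, detect alternating extrema, compute cycle amplitudes,
#' retain cycles whose amplitude exceeds the median amplitude (exact ties
#' with the median are retained; see Details), and report the median time
#' between consecutive retained maxima. An estimate above
#' `validity_bound_s` is flagged invalid (`valid = FALSE`) but still
#' reported — exclusion is left to cohort-level analyses such as
#' [scan_filter_widths()].
#'
#' @details The amplitude threshold exists to discard spurious
#' low-amplitude ripples between genuine arousal cycles. The comparison
#' uses a relative tolerance of 1e-9 so that signals whose cycles all
#' have identical amplitude (e.g. a pure sinusoid, where every amplitude
#' equals the median up to floating-point rounding) keep all their
#' cycles rather than a rounding-determined subset.
#'
#' @param series Gap-free `uniform_series` or numeric vector (1 Hz).
#' @param width_s Tent-filter width n_f in seconds.
#' @param validity_bound_s Longest period accepted as a genuine
#'   fluctuation estimate; longer estimates typically reflect the
#'   experimenter's wake-up interventions rather than spontaneous
#'   dynamics.
#' @param period_between `"retained"` (default): periods measured between
#'   consecutive retained maxima; `"all"`: between consecutive maxima
#'   regardless of retention.
#' @param dt Sample interval, seconds.
#'
#' @return An object of class `fluctuation_result`: list with `width_s`,
#'   `filtered`, `maxima_idx`, `minima_idx`, `cycles` (tibble `max_idx`,
#'   `amplitude`, `retained`), `periods_s`, `median_period_s`, `valid`,
#'   `n_cycles`, `n_retained`. [glance()] gives a one-row summary.
#' @export
#' @examples
#' t <- 0:7199
#' fl <- fluctuation_period(sin(2 * pi * t / 150), width_s = 50)
#' fl$median_period_s
fluctuation_period <- function(series, width_s, validity_bound_s = 300,
                               period_between = c("retained", "all"),
                               dt = 1) {
  period_between <- match.arg(period_between)
  filtered <- filter_tent(series, tent_kernel(width_s, dt))
  ext <- find_cycles(filtered)
  cyc <- cycle_amplitudes(filtered, ext$maxima_idx, ext$minima_idx)
  if (nrow(cyc) < 2) {
    abort(
      sprintf("Fewer than 2 cycles at filter width %g s.", width_s),
      class = "vigicouple_no_cycles"
    )
  }
  med <- median(cyc$amplitude)
  tol <- 1e-9 * max(abs(cyc$amplitude))
  cyc$retained <- cyc$amplitude > med - tol
  peak_idx <- if (period_between == "retained") {
    cyc$max_idx[cyc$retained]
  } else {
    cyc$max_idx
  }
  if (length(peak_idx) < 2) {
    abort(
      sprintf("Fewer than 2 retained maxima at filter width %g s.", width_s),
      class = "vigicouple_no_cycles"
    )
  }
  periods <- diff(peak_idx) * dt
  mp <- median(periods)
  structure(
    list(
      width_s = width_s,
      filtered = filtered,
      maxima_idx = ext$maxima_idx,
      minima_idx = ext$minima_idx,
      cycles = cyc,
      periods_s = periods,
      median_period_s = mp,
      valid = mp <= validity_bound_s,
      n_cycles = nrow(cyc),
      n_retained = sum(cyc$retained)
    ),
    class = "fluctuation_result"
  )
}

#' @export
print.fluctuation_result <- function(x, ...) {
  cat(sprintf(
    "Fluctuation at n_f = %g s: %d cycles, %d retained, median period %.1f s%s\n",
    x$width_s, x$n_cycles, x$n_retained, x$median_period_s,
    if (x$valid) "" else " (exceeds validity bound)"
  ))
  invisible(x)
}

#' @export
tidy.fluctuation_result <- function(x, ...) x$cycles

#' @export
glance.fluctuation_result <- function(x, ...) {
  tibble(
    width_s = x$width_s, n_cycles = x$n_cycles, n_retained = x$n_retained,
    median_period_s = x$median_period_s, valid = x$valid
  )
}

#' Correlate fluctuation periods with coupling strength across filter widths
#'
#' For each tent-filter width, computes every subject's median fluctuation
#' period and the Pearson correlation (with two-tailed p) between those
#' periods and the subjects' coupling strengths `C_max`. Subjects whose
#' period exceeds the validity bound at a given width are excluded from
#' that width's correlation (they are counted in `n_invalid`).
#'
#' @param series_list List of gap-free series (one per subject), all of
#'   the same signal.
#' @param cmax_values Numeric vector of per-subject `C_max`, same order.
#' @param widths_s Filter widths to scan, seconds.
#' @param validity_bound_s Passed to [fluctuation_period()].
#'
#' @return Tibble with one row per width: `width_s`, `n_valid`,
#'   `n_invalid`, `r`, `p`. Widths with fewer than 4 valid subjects get
#'   `NA` correlations.
#' @export
scan_filter_widths <- function(series_list, cmax_values,
                               widths_s = seq(10, 200, by = 10),
                               validity_bound_s = 300) {
  if (length(series_list) < 4) abort("Need at least 4 subjects to scan.")
  if (length(cmax_values) != length(series_list)) {
    abort("`cmax_values` must match `series_list` in length.")
  }
  purrr::map_dfr(widths_s, function(w) {
    res <- purrr::map(series_list, function(s) {
      tryCatch(
        fluctuation_period(s, w, validity_bound_s = validity_bound_s),
        vigicouple_no_cycles = function(e) NULL
      )
    })
    period <- purrr::map_dbl(res, function(r) {
      if (is.null(r)) NA_real_ else r$median_period_s
    })
    valid <- purrr::map_lgl(res, function(r) !is.null(r) && r$valid)
    n_invalid <- sum(!valid)
    if (sum(valid) < 4) {
      return(tibble(
        width_s = w, n_valid = sum(valid), n_invalid = n_invalid,
        r = NA_real_, p = NA_real_
      ))
    }
    ct <- cor_pearson(period[valid], cmax_values[valid])
    tibble(
      width_s = w, n_valid = sum(valid), n_invalid = n_invalid,
      r = ct$estimate, p = ct$p_two_tailed
    )
  })
}
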