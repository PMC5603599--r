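#' Lagged cross-correlation between two z-scored series
#'
#' Computes the biased (1/N) cross-correlation estimate
#' \deqn{r(k) = \frac{1}{N} \sum_t x(t)\, y(t+k)}
#' for integer lags k in `-max_lag_s .. +max_lag_s`. A positive lag means
#' `y` lags behind `x`; with `x` the cortical vigilance series and `y` an
#' autonomic series, positive lags mean the cortical signal leads. The sum
#' runs over the overlapping samples only and is always divided by the full
#' length N (biased estimator), which keeps `|r| <= 1` for z-scored inputs.
#'
#' The product sums are evaluated with FFTs (zero-padded, so linear rather
#' than circular correlation); the result is identical to the direct
#' lag-by-lag sum to within floating-point rounding.
#'
#' @param x,y `uniform_series` or numeric vectors, z-scored (see
#'   [zscore()]) and of equal length N > 2 * `max_lag_s`.
#' @param max_lag_s Maximum lag scanned, in seconds (samples).
#'
#' @return A tibble of class `lag_curve` with columns `lag_s`
#'   (-max_lag..+max_lag) and `r`.
#' @export
#' @examples
#' set.seed(1)
#' x <- zscore(rnorm(2000))
#' y <- zscore(c(rep(0, 20), x[1:1980]))  # y lags x by 20 s
#' curve <- cross_correlate(x, y)
#' curve$lag_s[which.max(abs(curve$r))]
cross_correlate <- function(x, y, max_lag_s = 100) {
  xv <- if (is.data.frame(x)) x$value else as.numeric(x)
  yv <- if (is.data.frame(y)) y$value else as.numeric(y)
  n <- length(xv)
  if (length(yv) != n) abort("`x` and `y` must have equal length.")
  max_lag_s <- as.integer(max_lag_s)
  if (n <= 2L * max_lag_s) {
    abort(sprintf("Series too short (N = %d) for max lag %d s.", n, max_lag_s))
  }
  m <- stats::nextn(2L * n, 2)
  fx <- fft(c(xv, numeric(m - n)))
  fy <- fft(c(yv, numeric(m - n)))
  cc <- Re(fft(Conj(fx) * fy, inverse = TRUE)) / m
  lags <- seq.int(-max_lag_s, max_lag_s)
  idx <- ifelse(lags >= 0, lags + 1L, m + lags + 1L)
  out <- tibble(lag_s = lags, r = cc[idx] / n)
  structure(
    out,
    x_label = if (is.data.frame(x)) series_label(x) else "x",
    y_label = if (is.data.frame(y)) series_label(y) else "y",
    n = n,
    class = c("lag_curve", class(tibble()))
  )
}

# Signed r at the lag of maximal |r| (default) or maximal signed r.
# Ties on the criterion: smallest |lag| wins, then the negative lag.
select_peak <- function(curve, mode = c("abs", "signed")) {
  mode <- match.arg(mode)
  crit <- if (mode == "abs") abs(curve$r) else curve$r
  if (all(curve$r == 0)) abort("All-zero correlation curve; cannot select a peak.")
  top <- which(crit == max(crit))
  top <- top[order(abs(curve$lag_s[top]), curve$lag_s[top])]
  i <- top[1]
  list(r = curve$r[i], lag_s = curve$lag_s[i])
}

#' Extract coupling strength and delay from a pair of lag curves
#'
#' For each curve the lag with the maximal absolute correlation is
#' selected (the signed coefficient at that lag is kept, so
#' anti-correlated coupling reports a negative coefficient). The summary
#' measures follow the coupling definitions used throughout the package:
#' `c_max = (|c_vhr| + |c_vscl|) / 2`,
#' `t_max_s = (|delay_vhr_s| + |delay_vscl_s|) / 2`, and subjects are
#' assigned to Group I ("with delay") when `t_max_s >= 1` s, else
#' Group II.
#'
#' @param curve_vhr,curve_vscl `lag_curve` objects from
#'   [cross_correlate()] for vigilance-vs-HR and vigilance-vs-SCL.
#' @param mode Peak rule: `"abs"` (default; signed r at the absolute
#'   extremum) or `"signed"` (maximal signed r).
#'
#' @return An object of class `coupling_result`: a list with elements
#'   `c_vhr`, `delay_vhr_s`, `c_vscl`, `delay_vscl_s`, `c_max`,
#'   `t_max_s`, `group` and `curves`. Use [tidy()] for a one-row tibble.
#' @export
extract_coupling <- function(curve_vhr, curve_vscl = NULL,
                             mode = c("abs", "signed")) {
  mode <- match.arg(mode)
  p1 <- select_peak(curve_vhr, mode)
  if (is.null(curve_vscl)) {
    p2 <- list(r = NA_real_, lag_s = NA_real_)
    c_max <- abs(p1$r)
    t_max <- abs(p1$lag_s)
  } else {
    p2 <- select_peak(curve_vscl, mode)
    c_max <- (abs(p1$r) + abs(p2$r)) / 2
    t_max <- (abs(p1$lag_s) + abs(p2$lag_s)) / 2
  }
  structure(
    list(
      c_vhr = p1$r, delay_vhr_s = p1$lag_s,
      c_vscl = p2$r, delay_vscl_s = p2$lag_s,
      c_max = c_max, t_max_s = t_max,
      group = assign_group(t_max),
      curves = list(vhr = curve_vhr, vscl = curve_vscl)
    ),
    class = "coupling_result"
  )
}

#' Delay-based group assignment
#'
#' Subjects with a mean absolute coupling delay of at least 1 s form
#' Group I ("with delay"); those below form Group II ("without
#' measurable delay").
#'
#' @param t_max_s Mean absolute delay in seconds (non-negative).
#' @return `"I"` or `"II"` (character, vectorised).
#' @export
assign_group <- function(t_max_s) {
  if (any(t_max_s < 0, na.rm = TRUE)) abort("`t_max_s` must be non-negative.")
  ifelse(t_max_s >= 1, "I", "II")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Cortico-autonomic coupling\n",
      "  C_VHR  = %6.3f at delay %+d s\n",
      "  C_VSCL = %s\n",
      "  C_max  = %6.3f   T_max = %.1f s   Group %s\n"
    ),
    x$c_vhr, as.integer(x$delay_vhr_s),
    if (is.na(x$c_vscl)) "   (absent)"
    else sprintf("%6.3f at delay %+d s", x$c_vscl, as.integer(x$delay_vscl_s)),
    x$c_max, x$t_max_s, x$group
  ))
  invisible(x)
}

#' @export
tidy.coupling_result <- function(x, ...) {
  tibble(
    c_vhr = x$c_vhr, delay_vhr_s = x$delay_vhr_s,
    c_vscl = x$c_vscl, delay_vscl_s = x$delay_vscl_s,
    c_max = x$c_max, t_max_s = x$t_max_s, group = x$group
  )
}

#' @export
glance.coupling_result <- function(x, ...) tidy(x)
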