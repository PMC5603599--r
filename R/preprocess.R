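#' Propagate EEG artifact marks into the autonomic channels
#'
#' Seconds marked as artifacts in the EEG are treated as artifacts in the
#' heart-rate and skin-conductance channels as well, so that all three
#' 1-Hz series share a common usable-time base.
#'
#' @param eeg_mask Logical vector (or `uniform_series` whose `mask` is
#'   used), `TRUE` at artifact seconds.
#' @param hr,scl `uniform_series` of equal length.
#'
#' @return A list with elements `hr` and `scl`: the input series with
#'   masks OR-ed with `eeg_mask`.
#' @export
propagate_artifacts <- function(eeg_mask, hr, scl) {
  if (is_uniform_series(eeg_mask) || is.data.frame(eeg_mask)) {
    eeg_mask <- eeg_mask$mask
  }
  eeg_mask <- as.logical(eeg_mask)
  if (length(eeg_mask) != nrow(hr) || length(eeg_mask) != nrow(scl)) {
    abort("`eeg_mask`, `hr` and `scl` must have equal length.")
  }
  or_into <- function(s) {
    s$mask <- s$mask | eeg_mask
    reseries(s, s)
  }
  list(hr = or_into(hr), scl = or_into(scl))
}

#' Heart rate from R-R intervals
#'
#' Converts an R-R interval stream into a 1-Hz heart-rate series. Each
#' second is assigned the heart rate 60000 / mean(R-R in ms) computed over
#' a window of three consecutive artifact-free 1-s segments. By default
#' the window slides (centred on the current second, so output keeps the
#' 1-s resolution); `window = "disjoint"` instead averages fixed blocks of
#' three segments, repeating the block value across its three seconds.
#' Any 3-segment window touching an artifact segment leaves the affected
#' seconds masked.
#'
#' @param rr A data frame with columns `time_s` (the 1-s segment each
#'   interval belongs to, starting at 0) and `rr_ms` (interval length,
#'   milliseconds), e.g. from [rr_series()].
#' @param segment_artifact Logical per 1-s segment; `TRUE` marks the
#'   segment as artifact. Defaults to segments with no R-R interval or
#'   with intervals outside the physiological 200-3000 ms range.
#' @param duration_s Length of the output series; defaults to the last
#'   segment seen in `rr` plus one.
#' @param window `"sliding"` (default) or `"disjoint"`.
#'
#' @return A `uniform_series` labelled `"HR"` (bpm).
#' @export
hr_from_rr <- function(rr, segment_artifact = NULL, duration_s = NULL,
                       window = c("sliding", "disjoint")) {
  window <- match.arg(window)
  if (!all(c("time_s", "rr_ms") %in% names(rr))) {
    abort("`rr` needs columns `time_s` and `rr_ms`.")
  }
  seg <- floor(rr$time_s)
  duration_s <- duration_s %||% (max(seg) + 1)
  n <- as.integer(duration_s)

  # per-segment mean interval and flag
  seg_mean <- rep(NA_real_, n)
  agg <- tapply(rr$rr_ms, seg, mean)
  idx <- as.integer(names(agg)) + 1L
  keep <- idx >= 1L & idx <= n
  seg_mean[idx[keep]] <- as.numeric(agg)[keep]

  out_of_range <- tapply(rr$rr_ms < 200 | rr$rr_ms > 3000, seg, any)
  seg_bad <- rep(TRUE, n)
  seg_bad[idx[keep]] <- as.logical(out_of_range)[keep]
  if (!is.null(segment_artifact)) {
    seg_bad <- seg_bad | rep_len(as.logical(segment_artifact), n)
  }
  seg_bad <- seg_bad | is.na(seg_mean)

  hr <- rep(NA_real_, n)
  if (window == "sliding") {
    for (t in seq_len(n)) {
      w <- t + (-1:1)
      if (t == 1L) w <- 1:3
      if (t == n) w <- (n - 2):n
      w <- w[w >= 1 & w <= n]
      if (length(w) == 3 && !any(seg_bad[w])) {
        hr[t] <- 60000 / mean(seg_mean[w])
      }
    }
  } else {
    starts <- seq(1L, n - 2L, by = 3L)
    for (s in starts) {
      w <- s:(s + 2L)
      if (!any(seg_bad[w])) hr[w] <- 60000 / mean(seg_mean[w])
    }
  }
  if (all(is.na(hr))) {
    warn("No artifact-free 3-segment window found; HR series is fully masked.")
  }
  uniform_series(hr, mask = is.na(hr), label = "HR")
}

#' Assemble an R-R interval stream
#'
#' @param rr_ms Positive R-R intervals in milliseconds, in temporal order.
#' @param t0_s Time of the first interval's segment, seconds.
#' @return A tibble with columns `time_s` (segment containing the interval,
#'   from cumulative interval times) and `rr_ms`.
#' @export
rr_series <- function(rr_ms, t0_s = 0) {
  if (any(rr_ms <= 0)) abort("R-R intervals must be positive.")
  onset_s <- t0_s + c(0, cumsum(rr_ms[-length(rr_ms)])) / 1000
  tibble(time_s = floor(onset_s), rr_ms = as.numeric(rr_ms))
}

#' Skin conductance level per 1-s segment
#'
#' Averages a 100-Hz skin-conductance recording into one value per EEG
#' segment (second). A trailing partial segment is dropped.
#'
#' @param samples Numeric vector of conductance samples (microsiemens).
#' @param fs Sampling rate in Hz (100 in the recordings this mirrors).
#' @return A `uniform_series` labelled `"SCL"`.
#' @export
scl_per_segment <- function(samples, fs = 100) {
  n_full <- length(samples) %/% fs
  if (n_full == 0L) abort("Fewer than one full second of SCL samples.")
  dropped <- length(samples) - n_full * fs
  if (dropped > 0) {
    rlang::inform(sprintf("Dropping %d trailing SCL sample(s) (partial segment).", dropped))
  }
  m <- matrix(samples[seq_len(n_full * fs)], nrow = fs)
  uniform_series(colMeans(m), label = "SCL")
}

#' Replace artifact seconds by the subject mean
#'
#' Masked samples are replaced by the mean of the unmasked samples of the
#' same series, and the mask is cleared, producing the gap-free series the
#' cross-correlation and fluctuation stages require. Unmasked samples are
#' never altered, so the series mean is preserved exactly.
#'
#' @param series A `uniform_series`.
#' @return The gap-filled `uniform_series` with attribute `n_filled`.
#' @export
fill_missing <- function(series) {
  validate_uniform_series(series)
  if (all(series$mask)) abort("Cannot fill a fully masked series.")
  m <- mean(series$value[!series$mask])
  n_filled <- sum(series$mask)
  series$value[series$mask] <- m
  series$mask <- rep(FALSE, nrow(series))
  out <- reseries(series, series)
  attr(out, "n_filled") <- n_filled
  out
}

#' Normalise a series to zero mean and unit variance
#'
#' Uses the population (1/N) standard deviation, matching the biased
#' cross-correlation estimator of [cross_correlate()] so that the zero-lag
#' autocorrelation of a z-scored series is exactly 1.
#'
#' @param series A gap-free `uniform_series` (or plain numeric vector).
#' @return Same type as the input, standardised.
#' @export
zscore <- function(series) {
  v <- if (is.data.frame(series)) series$value else as.numeric(series)
  s <- pop_sd(v)
  if (!is.finite(s) || s == 0) abort("Cannot z-score a constant series.")
  z <- (v - mean(v)) / s
  if (is.data.frame(series)) {
    series$value <- z
    reseries(series, series)
  } else {
    z
  }
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
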