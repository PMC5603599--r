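#' Epoch stream container
#'
#' ERP epochs travel as a tibble with one row per stimulus: columns
#' `epoch_idx`, `onset_s`, `stimulus_type` (`"standard"` / `"deviant"`),
#' `stage` (vigilance score 1-7 at stimulus onset), `channel`,
#' `follows_deviant`, and `samples`, a list-column of 900 amplitude
#' values (microvolts, 1 kHz) spanning -100..+799 ms around onset
#' (sample 101 is stimulus onset).
#'
#' @name erp_epochs
NULL

EPOCH_LEN <- 900L
EPOCH_PRE <- 100L

epoch_time_ms <- function() seq_len(EPOCH_LEN) - EPOCH_PRE - 1L

#' Apply the epoch selection rules
#'
#' Drops (in this order): standard stimuli that immediately follow a
#' deviant; epochs whose amplitude exceeds +/-100 microvolts at any
#' sample of the analysed channel; epochs outside an optional vigilance
#' stage restriction (e.g. `stage_restriction = 6` keeps only stage A1).
#'
#' @param epochs Epoch tibble (see [erp_epochs]).
#' @param stage_restriction Optional vigilance score(s) 1-7 to keep.
#' @param reject_uv Absolute rejection threshold in microvolts.
#' @return The filtered epoch tibble, with attribute `n_dropped` holding
#'   counts per rule.
#' @export
select_epochs <- function(epochs, stage_restriction = NULL, reject_uv = 100) {
  n0 <- nrow(epochs)
  keep1 <- !(epochs$stimulus_type == "standard" & epochs$follows_deviant)
  epochs <- epochs[keep1, ]
  over <- purrr::map_lgl(epochs$samples, function(s) any(abs(s) > reject_uv))
  n_post_dev <- n0 - nrow(epochs)
  epochs <- epochs[!over, ]
  n_reject <- sum(over)
  n_stage <- 0L
  if (!is.null(stage_restriction)) {
    in_stage <- epochs$stage %in% stage_restriction
    n_stage <- sum(!in_stage)
    epochs <- epochs[in_stage, ]
  }
  if (nrow(epochs) == 0L) warn("Epoch selection left no epochs.")
  attr(epochs, "n_dropped") <- c(
    post_deviant_standard = n_post_dev,
    amplitude_reject = n_reject,
    stage_restriction = n_stage
  )
  epochs
}

#' Baseline-correct and average epochs
#'
#' Subtracts each epoch's mean over the 100 ms pre-stimulus interval,
#' then averages point-wise. At least `min_epochs` epochs (50 by
#' default) are required for a valid average.
#'
#' @param epochs Epoch tibble, typically after [select_epochs()].
#' @param min_epochs Minimum number of epochs required.
#' @param condition Optional label describing the averaged condition.
#' @return An object of class `erp_average`: list with `waveform`
#'   (microvolts, 900 samples), `time_ms`, `n_epochs`, `condition`.
#' @export
baseline_and_average <- function(epochs, min_epochs = 50, condition = NULL) {
  n <- nrow(epochs)
  if (n < min_epochs) {
    abort(
      sprintf("Only %d epochs; at least %d required for averaging.", n, min_epochs),
      class = "vigicouple_invalid_average",
      n_epochs = n
    )
  }
  m <- do.call(rbind, epochs$samples)
  if (ncol(m) != EPOCH_LEN) abort("Epochs must have 900 samples each.")
  base <- rowMeans(m[, seq_len(EPOCH_PRE), drop = FALSE])
  m <- m - base
  structure(
    list(
      waveform = colMeans(m),
      time_ms = epoch_time_ms(),
      n_epochs = n,
      condition = condition
    ),
    class = "erp_average"
  )
}

#' @export
print.erp_average <- function(x, ...) {
  cat(sprintf(
    "ERP average%s: %d epochs, range %.2f .. %.2f uV\n",
    if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
    x$n_epochs, min(x$waveform), max(x$waveform)
  ))
  invisible(x)
}

#' @export
tidy.erp_average <- function(x, ...) {
  tibble(time_ms = x$time_ms, amplitude_uv = x$waveform)
}

# most extreme local extremum of `w` restricted to indices `idx`;
# direction -1 = minimum (N1), +1 = maximum (P2)
local_extremum <- function(w, idx, direction) {
  n <- length(w)
  interior <- idx[idx > 1 & idx < n]
  cand <- interior[
    direction * w[interior] > direction * w[interior - 1] &
      direction * w[interior] > direction * w[interior + 1]
  ]
  if (length(cand) == 0) {
    ends <- range(idx)
    i <- ends[which.max(direction * w[ends])]
    list(idx = i, fallback = TRUE)
  } else {
    list(idx = cand[which.max(direction * w[cand])], fallback = FALSE)
  }
}

#' Extract N1 and P2 peaks from an averaged waveform
#'
#' N1 is the most negative local extremum within its search window, P2
#' the most positive within its own. Peak amplitude is the mean of the
#' waveform over the peak +/-10 ms (N1) or +/-20 ms (P2), truncated at
#' the epoch edges; latency is the peak sample time. When a window
#' contains no interior local extremum the more extreme window endpoint
#' is used and the component's fallback flag is set.
#'
#' The default windows (N1 70-140 ms, P2 140-260 ms) bracket the
#' latencies typical of ignored auditory oddball N1 (~90 ms) and P2
#' (~185-215 ms) and are configurable.
#'
#' @param avg An `erp_average`.
#' @param windows Named list with two-element ms ranges `n1` and `p2`.
#' @param halfwin_ms Named vector of amplitude half-windows in ms.
#' @return One-row tibble of class `erp_peaks`: `n1_amp_uv`,
#'   `n1_lat_ms`, `n1_fallback`, `p2_amp_uv`, `p2_lat_ms`,
#'   `p2_fallback`, `n_epochs`.
#' @export
detect_peaks <- function(avg,
                         windows = list(n1 = c(70, 140), p2 = c(140, 260)),
                         halfwin_ms = c(n1 = 10, p2 = 20)) {
  if (!inherits(avg, "erp_average")) abort("`avg` must be an `erp_average`.")
  w <- avg$waveform
  tms <- avg$time_ms
  one <- function(comp, direction) {
    win <- windows[[comp]]
    if (win[1] < 0 || win[2] > max(tms)) abort("Search window outside the epoch.")
    idx <- which(tms >= win[1] & tms <= win[2])
    pk <- local_extremum(w, idx, direction)
    half <- halfwin_ms[[comp]]
    lo <- max(1L, pk$idx - half)
    hi <- min(length(w), pk$idx + half)
    list(amp = mean(w[lo:hi]), lat = tms[pk$idx], fallback = pk$fallback)
  }
  n1 <- one("n1", -1)
  p2 <- one("p2", +1)
  out <- tibble(
    n1_amp_uv = n1$amp, n1_lat_ms = as.numeric(n1$lat), n1_fallback = n1$fallback,
    p2_amp_uv = p2$amp, p2_lat_ms = as.numeric(p2$lat), p2_fallback = p2$fallback,
    n_epochs = avg$n_epochs
  )
  class(out) <- c("erp_peaks", class(out))
  out
}

#' Per-condition ERP peak table for one subject
#'
#' Runs selection, averaging and peak extraction for every combination
#' of channel and stimulus type present in the epoch stream, optionally
#' restricted to a vigilance stage. Conditions failing the 50-epoch
#' minimum are reported with `NA` peaks and their epoch count.
#'
#' @param epochs Epoch tibble.
#' @param stage_restriction Optional stage score(s) passed to
#'   [select_epochs()].
#' @param windows,halfwin_ms Passed to [detect_peaks()].
#' @param min_epochs Passed to [baseline_and_average()].
#' @return Tibble with one row per (channel, stimulus_type):
#'   peak columns plus `valid` (logical).
#' @export
erp_condition_peaks <- function(epochs, stage_restriction = NULL,
                                windows = list(n1 = c(70, 140), p2 = c(140, 260)),
                                halfwin_ms = c(n1 = 10, p2 = 20),
                                min_epochs = 50) {
  sel <- select_epochs(epochs, stage_restriction = stage_restriction)
  combos <- tidyr::expand_grid(
    channel = unique(sel$channel),
    stimulus_type = c("standard", "deviant")
  )
  purrr::pmap_dfr(combos, function(channel, stimulus_type) {
    sub <- sel[sel$channel == channel & sel$stimulus_type == stimulus_type, ]
    res <- tryCatch(
      {
        avg <- baseline_and_average(sub, min_epochs = min_epochs,
                                    condition = paste(channel, stimulus_type))
        pk <- detect_peaks(avg, windows = windows, halfwin_ms = halfwin_ms)
        dplyr::mutate(pk, valid = TRUE)
      },
      vigicouple_invalid_average = function(e) {
        tibble(
          n1_amp_uv = NA_real_, n1_lat_ms = NA_real_, n1_fallback = NA,
          p2_amp_uv = NA_real_, p2_lat_ms = NA_real_, p2_fallback = NA,
          n_epochs = e$n_epochs, valid = FALSE
        )
      }
    )
    dplyr::bind_cols(
      tibble(channel = channel, stimulus_type = stimulus_type),
      res
    )
  })
}
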