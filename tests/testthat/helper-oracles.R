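# Independent oracles and small fixtures used across the suite.

# Direct O(N * L) lag-by-lag cross-correlation sum, the reference the FFT
# implementation is checked against.
crosscorr_loop <- function(x, y, max_lag = 100) {
  n <- length(x)
  sapply(-max_lag:max_lag, function(k) {
    if (k >= 0) {
      idx <- seq_len(n - k)
      sum(x[idx] * y[idx + k]) / n
    } else {
      idx <- seq_len(n + k)
      sum(x[idx - k] * y[idx]) / n
    }
  })
}

# Tiny deterministic sinusoid series
sinusoid_series <- function(period_s, duration_s, amplitude = 1, phase = 0) {
  t <- seq_len(duration_s) - 1
  amplitude * sin(2 * pi * t / period_s + phase)
}

# A z-scored white-noise uniform series
zs_noise <- function(n, seed) {
  set.seed(seed)
  zscore(uniform_series(rnorm(n), label = "x"))
}

# Noise-free epoch tibble: `n` copies of a waveform (900 samples)
template_epochs <- function(waveform, n, channel = "Fz",
                            stimulus_type = "standard", stage = 6L,
                            follows_deviant = FALSE) {
  tibble::tibble(
    epoch_idx = seq_len(n),
    onset_s = seq_len(n) * 1.1,
    stimulus_type = stimulus_type,
    stage = stage,
    channel = channel,
    follows_deviant = rep_len(follows_deviant, n),
    samples = replicate(n, waveform, simplify = FALSE)
  )
}

# Gaussian ERP component on the -100..799 ms grid
gauss_component <- function(lat_ms, amp_uv, width_ms = 10) {
  tms <- -100:799
  amp_uv * exp(-0.5 * ((tms - lat_ms) / width_ms)^2)
}
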