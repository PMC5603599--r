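#' Parameters of the synthetic oddball ERP stream
#'
#' Describes an ignored auditory oddball sequence: stimuli arrive with
#' inter-stimulus intervals drawn uniformly from `isi_range_ms`, are
#' deviant with probability `p_deviant` (0.2, i.e. the classic 80/20
#' stream), and each stimulus evokes a negative Gaussian N1 component
#' plus a positive Gaussian P2 component whose joint amplitude is scaled
#' by the vigilance stage at stimulus onset via `vigilance_modulation`.
#'
#' @param n_stimuli Number of stimuli in the train.
#' @param isi_range_ms Two-element inter-stimulus interval range (ms).
#' @param p_deviant Deviant probability, in (0, 1).
#' @param n1_latency_ms,p2_latency_ms Component peak latencies (ms
#'   post-stimulus, inside the 0-799 ms epoch span).
#' @param n1_amp_uv,p2_amp_uv Signed component peak amplitudes
#'   (microvolts; N1 negative, P2 positive).
#' @param template_width_ms Gaussian SD of each component template (ms).
#' @param noise_sd_uv White noise SD per sample (microvolts).
#' @param vigilance_modulation Length-7 vector mapping stage score 1-7
#'   to a template scale factor. The default attenuates components as
#'   vigilance declines (scale 0.5 at sleep onset up to 1 in active
#'   wakefulness).
#' @param channels Channels to synthesise (same template, independent
#'   noise).
#' @param seed Integer seed.
#'
#' @return A validated list of class `erp_synth_params`.
#' @export
erp_synth_params <- function(n_stimuli = 1000,
                             isi_range_ms = c(900, 1400),
                             p_deviant = 0.2,
                             n1_latency_ms = 100,
                             p2_latency_ms = 200,
                             n1_amp_uv = -5,
                             p2_amp_uv = 6,
                             template_width_ms = 15,
                             noise_sd_uv = 5,
                             vigilance_modulation = 0.5 + 0.5 * (0:6) / 6,
                             channels = c("Fz", "Cz"),
                             seed = 1L) {
  p <- as.list(environment())
  if (p$p_deviant <= 0 || p$p_deviant >= 1) abort("`p_deviant` must be in (0, 1).")
  if (p$n1_latency_ms < 0 || p$n1_latency_ms > 799 ||
      p$p2_latency_ms < 0 || p$p2_latency_ms > 799) {
    abort("Component latencies must lie within the 0-799 ms epoch span.")
  }
  if (length(p$vigilance_modulation) != 7) {
    abort("`vigilance_modulation` must map all 7 stages.")
  }
  structure(p, class = "erp_synth_params")
}

#' Evoked-response template of the generator
#'
#' The noise-free single-trial waveform: negative Gaussian N1 plus
#' positive Gaussian P2, zero before stimulus onset apart from the
#' Gaussian tails.
#'
#' @param params An [erp_synth_params()] object.
#' @return Numeric vector of 900 microvolt values (-100..799 ms).
#' @export
erp_template <- function(params) {
  tms <- epoch_time_ms()
  g <- function(lat, amp) amp * exp(-0.5 * ((tms - lat) / params$template_width_ms)^2)
  g(params$n1_latency_ms, params$n1_amp_uv) +
    g(params$p2_latency_ms, params$p2_amp_uv)
}

#' Generate an oddball ERP epoch stream
#'
#' Stimulus onsets follow the ISI distribution; each epoch is the
#' component template scaled by `vigilance_modulation[stage at onset]`
#' plus white noise. Standards following a deviant are flagged via
#' `follows_deviant` (they are excluded later by [select_epochs()], not
#' here). The vigilance series must cover the whole stimulus train.
#'
#' @param params An [erp_synth_params()] object.
#' @param vigilance A `uniform_series` of stage scores 1-7.
#' @return An epoch tibble (see [erp_epochs]).
#' @export
generate_erp_stream <- function(params, vigilance) {
  stopifnot(inherits(params, "erp_synth_params"))
  set.seed(params$seed)
  generate_erp_stream_impl(params, vigilance)
}

generate_erp_stream_impl <- function(params, vigilance) {
  n <- params$n_stimuli
  isi_ms <- runif(n, params$isi_range_ms[1], params$isi_range_ms[2])
  onset_s <- (1000 + cumsum(c(0, isi_ms[-n]))) / 1000
  if (max(onset_s) + 0.8 > nrow(vigilance)) {
    abort("Vigilance series does not cover the stimulus train.")
  }
  type <- ifelse(runif(n) < params$p_deviant, "deviant", "standard")
  follows <- c(FALSE, type[-n] == "deviant")
  stage <- as.integer(vigilance$value[floor(onset_s) + 1])
  scale <- params$vigilance_modulation[stage]
  template <- erp_template(params)

  rows <- purrr::map(params$channels, function(ch) {
    noise <- matrix(rnorm(n * EPOCH_LEN, 0, params$noise_sd_uv), nrow = n)
    samples <- purrr::map(seq_len(n), function(i) scale[i] * template + noise[i, ])
    tibble(
      epoch_idx = seq_len(n),
      onset_s = onset_s,
      stimulus_type = type,
      stage = stage,
      channel = ch,
      follows_deviant = follows,
      samples = samples
    )
  })
  dplyr::bind_rows(rows)
}
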