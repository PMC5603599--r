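#' Parameters of the synthetic coupled-recording generator
#'
#' Defines the ground truth for a simulated 2-h resting-state recording:
#' a slow latent arousal process (sinusoid of period `v_period_s` in the
#' infra-slow ~0.005 Hz range, plus Ornstein-Uhlenbeck noise) that is
#' quantised into the 7 ordinal vigilance stages, drives heart rate at a
#' configurable delay (plus respiratory sinus arrhythmia), and drives an
#' inert, low-pass-filtered skin conductance level. Subjects lingering at
#' the sleep-onset stage for `wakeup_after_s` consecutive seconds are
#' "woken up" (the latent level resets towards wakefulness) and the event
#' is counted, emulating the experimenter's intervention.
#'
#' @param duration_s Recording length in seconds (default 7200 = 2 h).
#' @param v_period_s Latent arousal period in seconds (~190 s, i.e.
#'   ~0.005 Hz).
#' @param coupling_gain_hr HR gain, bpm per unit latent arousal.
#' @param coupling_gain_scl SCL gain, microsiemens per unit arousal.
#' @param delay_hr_s,delay_scl_s Lag of the autonomic response behind the
#'   cortical signal, seconds (0-100).
#' @param rsa_amplitude_bpm Amplitude of the respiratory sinus arrhythmia
#'   component of HR.
#' @param resp_freq_hz Respiration frequency (Hz).
#' @param scl_time_constant_s First-order time constant of the skin
#'   conductance response (inert ~50 s by default).
#' @param noise_sd_v Stationary SD of the Ornstein-Uhlenbeck noise added
#'   to the latent arousal (unitless, relative to the unit sinusoid).
#' @param ou_tau_s Correlation time of the OU noise, seconds.
#' @param drift_per_hr Slow downward drift of the latent arousal per
#'   hour (unitless), modelling the natural decline of wakefulness over
#'   the session; this is what eventually brings subjects to the
#'   sleep-onset stage and triggers wake-up interventions.
#' @param wake_recovery_tau_s Time constant on which the wake-up reset
#'   relaxes back into the ongoing dynamics (minutes — an aroused
#'   subject does not fall back asleep within seconds).
#' @param sleep_onset_after_s Consecutive seconds of drowsiness (stage
#'   score <= 2) after which sleep onset consolidates: the latent then
#'   relaxes into the sleep-onset band and stays there instead of
#'   flickering out with every fluctuation, until the wake-up
#'   intervention (or a strong arousal surge) ends the episode.
#' @param sleep_consolidation_tau_s Relaxation time constant of that
#'   consolidation.
#' @param amp_mod_depth,amp_mod_period_s Slow waxing-and-waning envelope
#'   of the arousal fluctuation (depth in [0, 1)): vigilance
#'   fluctuations come in bouts rather than at constant amplitude.
#' @param hr_fluct_period_s,hr_fluct_amp_bpm Intrinsic cardiovascular
#'   fluctuation of HR (vasomotor band, period ~100 s), independent of
#'   the cortical drive.
#' @param noise_sd_hr White measurement noise SD of HR (bpm).
#' @param noise_sd_scl Stationary SD of the spontaneous electrodermal
#'   fluctuation (microsiemens), an Ornstein-Uhlenbeck process with
#'   correlation time `scl_fluct_tau_s` entering the skin conductance
#'   drive before the low-pass response — slow and smooth, unlike
#'   sensor noise, and uncorrelated with the cortical signal.
#' @param scl_fluct_tau_s Correlation time of that fluctuation,
#'   seconds.
#' @param scl_meas_noise_us White sensor noise added to the recorded
#'   SCL (microsiemens; small).
#' @param artifact_fraction Fraction of seconds masked as artifacts
#'   (shared across channels, as EEG artifacts propagate).
#' @param wakeup_after_s Consecutive seconds at the sleep-onset stage
#'   before the wake-up intervention fires (default 300 s).
#' @param hr_baseline_bpm,scl_baseline_us Signal baselines.
#' @param seed Integer seed; the whole subject is a deterministic
#'   function of the parameter set.
#'
#' @return A validated list of class `synth_params`.
#' @export
synth_params <- function(duration_s = 7200,
                         v_period_s = 190,
                         coupling_gain_hr = 1.2,
                         coupling_gain_scl = 0.35,
                         delay_hr_s = 8,
                         delay_scl_s = 8,
                         rsa_amplitude_bpm = 2,
                         resp_freq_hz = 0.25,
                         scl_time_constant_s = 50,
                         amp_mod_depth = 0.5,
                         amp_mod_period_s = 1600,
                         hr_fluct_period_s = 100,
                         hr_fluct_amp_bpm = 1.5,
                         noise_sd_v = 0.4,
                         ou_tau_s = 5,
                         drift_per_hr = -2,
                         wake_recovery_tau_s = 300,
                         sleep_onset_after_s = 90,
                         sleep_consolidation_tau_s = 30,
                         noise_sd_hr = 3,
                         noise_sd_scl = 0.7,
                         scl_fluct_tau_s = 200,
                         scl_meas_noise_us = 0.02,
                         artifact_fraction = 0.05,
                         wakeup_after_s = 300,
                         hr_baseline_bpm = 62,
                         scl_baseline_us = 3,
                         seed = 1L) {
  p <- as.list(environment())
  if (p$duration_s <= 2 * p$v_period_s) {
    abort("`duration_s` must exceed twice `v_period_s`.")
  }
  if (p$delay_hr_s < 0 || p$delay_scl_s < 0) abort("Delays must be >= 0.")
  if (p$delay_hr_s > 100 || p$delay_scl_s > 100) {
    abort("Delays must be within the 100 s cross-correlation scan range.")
  }
  if (p$artifact_fraction < 0 || p$artifact_fraction >= 0.5) {
    abort("`artifact_fraction` must be in [0, 0.5).")
  }
  structure(p, class = "synth_params")
}

#' Parameter-recovery test-bed condition
#'
#' A clean-coupling variant of [synth_params()] used to verify that the
#' delay estimator recovers planted lags: strong gains, low measurement
#' noise, a fast-responding skin conductance channel (time constant
#' 0.5 s, so the planted lag is the true lag of the signal rather than
#' being confounded with electrodermal inertia), no session drift and
#' damped respiratory/vasomotor components. The default, realistic
#' condition keeps the inert 50 s SCL response; under that inertness
#' the cross-correlation peak of SCL is shifted by the filter itself,
#' which is a property of the signal, not an estimator error.
#'
#' @param delay_s Planted cortico-autonomic delay, applied to both HR
#'   and SCL.
#' @param seed Integer seed.
#' @param ... Further overrides passed to [synth_params()].
#' @return A `synth_params` object.
#' @export
recovery_params <- function(delay_s = 0, seed = 1L, ...) {
  args <- list(
    delay_hr_s = delay_s,
    delay_scl_s = delay_s,
    coupling_gain_hr = 4,
    coupling_gain_scl = 1,
    scl_time_constant_s = 0.5,
    noise_sd_hr = 0.5,
    noise_sd_scl = 0.05,
    rsa_amplitude_bpm = 0.5,
    hr_fluct_amp_bpm = 0.3,
    noise_sd_v = 0.2,
    drift_per_hr = 0,
    artifact_fraction = 0.02,
    seed = seed
  )
  args <- utils::modifyList(args, list(...))
  do.call(synth_params, args)
}

#' Generate the latent arousal process
#'
#' `A(t) = sin(2 pi t / v_period_s) + OU(t)` at 1 Hz, with wake-up
#' interventions: the series is quantised into 7 stages by equally
#' spaced thresholds over its range, and whenever the quantised stage
#' would remain at the sleep-onset stage (score 1) for `wakeup_after_s`
#' consecutive seconds, the latent level is reset to the series' upper
#' quartile (relaxing back on the OU time scale, so all coupled signals
#' react coherently) and one falling-asleep event is counted.
#'
#' @param params A [synth_params()] object.
#' @return A `uniform_series` (label `"A"`, zero mask) with attributes
#'   `falling_asleep_count` and `stage_breaks` (the 8 quantisation
#'   thresholds).
#' @export
generate_latent_arousal <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  generate_latent_arousal_impl(params)
}

# RNG-stateful core, called with the subject seed already set.
#
# The raw drive is sinusoid * slow envelope + OU noise + session drift.
# Quantisation thresholds are fixed from the raw drive. On top of it a
# sequential state machine emulates the wake-sleep transition: sustained
# drowsiness (stage <= 2 for sleep_onset_after_s) consolidates into a
# sleep-onset episode (the level relaxes into the stage-1 band and stays),
# and after wakeup_after_s seconds at stage 1 the experimenter wakes the
# subject (level resets to the upper quartile, decaying back on
# wake_recovery_tau_s). With zero noise, drift and envelope depth the
# machinery never engages and A is the exact sinusoid.
generate_latent_arousal_impl <- function(params) {
  n <- as.integer(params$duration_s)
  t <- seq_len(n) - 1
  envelope <- 1 + (params$amp_mod_depth %||% 0) *
    sin(2 * pi * t / (params$amp_mod_period_s %||% Inf))
  osc <- envelope * sin(2 * pi * t / params$v_period_s)
  ou <- ou_noise(n, params$noise_sd_v, params$ou_tau_s)
  drift <- (params$drift_per_hr %||% 0) * t / 3600
  raw <- osc + ou + drift

  breaks <- seq(min(raw), max(raw), length.out = 8)
  q75 <- unname(quantile(raw, 0.75))
  th_sleep <- breaks[2]    # below: stage-1 (sleep onset)
  th_drowsy <- breaks[3]   # below: stage <= 2 (drowsiness or deeper)
  th_arouse <- breaks[5]   # sustained drive above this ends a sleep episode
  sleep_target <- (breaks[1] + breaks[2]) / 2
  lambda_w <- exp(-1 / (params$wake_recovery_tau_s %||% 600))
  alpha_c <- 1 - exp(-1 / (params$sleep_consolidation_tau_s %||% 30))
  onset_after <- params$sleep_onset_after_s %||% 90
  arouse_sustain <- 45L

  x <- numeric(n)
  x[1] <- raw[1]
  w <- 0
  run_low <- 0L
  run_sleep <- 0L
  run_arouse <- 0L
  asleep <- FALSE
  falling_asleep <- 0L
  for (i in seq_len(n)[-1]) {
    w <- w * lambda_w
    base <- raw[i] + w
    if (asleep) {
      # a strong, sustained arousal surge wakes the subject spontaneously
      run_arouse <- if (base > th_arouse) run_arouse + 1L else 0L
      if (run_arouse >= arouse_sustain) {
        asleep <- FALSE
        run_arouse <- 0L
      }
    }
    x[i] <- if (asleep) x[i - 1] + alpha_c * (sleep_target - x[i - 1]) else base
    run_low <- if (x[i] < th_drowsy) run_low + 1L else 0L
    if (!asleep && run_low >= onset_after) asleep <- TRUE
    run_sleep <- if (x[i] < th_sleep) run_sleep + 1L else 0L
    if (run_sleep >= params$wakeup_after_s) {
      falling_asleep <- falling_asleep + 1L
      w <- q75 - raw[i]
      x[i] <- q75
      asleep <- FALSE
      run_low <- 0L
      run_sleep <- 0L
      run_arouse <- 0L
    }
  }

  out <- uniform_series(x, mask = FALSE, label = "A")
  attr(out, "falling_asleep_count") <- falling_asleep
  attr(out, "stage_breaks") <- breaks
  out
}

ou_noise <- function(n, sd, tau) {
  if (sd == 0) return(numeric(n))
  phi <- exp(-1 / tau)
  innov_sd <- sd * sqrt(1 - phi^2)
  x1 <- rnorm(1, 0, sd)
  eps <- rnorm(n - 1, 0, innov_sd)
  rest <- stats::filter(eps, phi, method = "recursive", init = x1)
  c(x1, as.numeric(rest))
}

# equally spaced thresholds over the series range -> ordinal scores 1..7
quantize_stage <- function(a, breaks) {
  s <- findInterval(a, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(s, 1L), 7L)
}

shift_lagged <- function(x, lag_s) {
  lag_s <- as.integer(round(lag_s))
  if (lag_s == 0) return(x)
  c(rep(x[1], lag_s), x[seq_len(length(x) - lag_s)])
}

#' Generate one synthetic subject record
#'
#' Produces the three coupled 1-Hz series: vigilance `V` (latent arousal
#' quantised to stage scores 1-7), heart rate
#' `HR(t) = baseline + gain * A(t - delay_hr) + RSA + noise`, and skin
#' conductance `SCL(t)` as a first-order low-pass (time constant
#' `scl_time_constant_s`) of `baseline + gain * A(t - delay_scl)` plus
#' noise. A common random artifact mask covering `artifact_fraction` of
#' the seconds is applied to all three channels. Optionally an oddball
#' ERP epoch stream is generated against the vigilance series.
#'
#' All randomness flows through one generator seeded from
#' `params$seed`, so identical parameters give a bit-identical record.
#'
#' @param params A [synth_params()] object.
#' @param erp_params Optional [erp_synth_params()]; when given, epochs
#'   are attached to the record.
#' @param subject_id Identifier stored in the record.
#' @return An object of class `subject_record`: list with `subject_id`,
#'   `v`, `hr`, `scl` (`uniform_series`), `epochs` (tibble or `NULL`),
#'   `falling_asleep_count`, `params`.
#' @export
generate_subject <- function(params, erp_params = NULL, subject_id = "S01") {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  n <- as.integer(params$duration_s)
  t <- seq_len(n) - 1

  arousal <- generate_latent_arousal_impl(params)
  a <- arousal$value
  breaks <- attr(arousal, "stage_breaks")

  v <- quantize_stage(a, breaks)

  hr <- params$hr_baseline_bpm +
    params$coupling_gain_hr * shift_lagged(a, params$delay_hr_s) +
    params$rsa_amplitude_bpm * sin(2 * pi * params$resp_freq_hz * t) +
    (params$hr_fluct_amp_bpm %||% 0) *
      sin(2 * pi * t / (params$hr_fluct_period_s %||% Inf)) +
    rnorm(n, 0, params$noise_sd_hr)

  scl_drive <- params$scl_baseline_us +
    params$coupling_gain_scl * shift_lagged(a, params$delay_scl_s) +
    ou_noise(n, params$noise_sd_scl, params$scl_fluct_tau_s %||% 200)
  alpha <- 1 - exp(-1 / params$scl_time_constant_s)
  scl <- as.numeric(stats::filter(alpha * scl_drive, 1 - alpha,
                                  method = "recursive",
                                  init = scl_drive[1]))
  scl <- scl + rnorm(n, 0, params$scl_meas_noise_us %||% 0)

  n_art <- round(params$artifact_fraction * n)
  mask <- rep(FALSE, n)
  if (n_art > 0) mask[sample.int(n, n_art)] <- TRUE

  epochs <- NULL
  v_series <- uniform_series(v, mask = mask, label = "V")
  if (!is.null(erp_params)) {
    epochs <- generate_erp_stream_impl(erp_params, v_series)
  }

  structure(
    list(
      subject_id = subject_id,
      v = v_series,
      hr = uniform_series(hr, mask = mask, label = "HR"),
      scl = uniform_series(scl, mask = mask, label = "SCL"),
      epochs = epochs,
      falling_asleep_count = attr(arousal, "falling_asleep_count"),
      params = params
    ),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf(
    "Subject %s: %d s recording, %d falling-asleep event(s)%s\n",
    x$subject_id, nrow(x$v), x$falling_asleep_count,
    if (is.null(x$epochs)) "" else sprintf(", %d ERP epochs", nrow(x$epochs))
  ))
  invisible(x)
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject seeds are drawn deterministically from the cohort seed,
#' so the whole cohort is reproducible from one integer.
#'
#' @param n_subjects Number of subjects.
#' @param params Baseline [synth_params()]; per-subject overrides can be
#'   supplied through `vary`, a function `(index) -> named list` merged
#'   into the parameters of each subject.
#' @param erp_params Optional baseline [erp_synth_params()]; `vary_erp`
#'   works like `vary`.
#' @param seed Cohort seed.
#' @param vary,vary_erp Optional per-subject parameter override
#'   functions.
#' @return List of `subject_record`s.
#' @export
generate_cohort <- function(n_subjects, params = synth_params(),
                            erp_params = NULL, seed = 1L,
                            vary = NULL, vary_erp = NULL) {
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  purrr::map(seq_len(n_subjects), function(i) {
    p <- params
    if (!is.null(vary)) p <- utils::modifyList(p, vary(i))
    p$seed <- subject_seeds[i]
    class(p) <- "synth_params"
    ep <- erp_params
    if (!is.null(ep)) {
      if (!is.null(vary_erp)) ep <- utils::modifyList(ep, vary_erp(i))
      ep$seed <- subject_seeds[i] + 1L
      class(ep) <- "erp_synth_params"
    }
    generate_subject(p, erp_params = ep,
                     subject_id = sprintf("S%02d", i))
  })
}
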