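test_that("the noiseless latent process is an exact sinusoid", {
  p <- synth_params(noise_sd_v = 0, drift_per_hr = 0, amp_mod_depth = 0,
                    v_period_s = 190, duration_s = 1900, seed = 1)
  a <- generate_latent_arousal(p)
  t <- 0:1899
  expect_equal(a$value, sin(2 * pi * t / 190), tolerance = 1e-12)
  expect_equal(attr(a, "falling_asleep_count"), 0L)
  expect_false(any(a$mask))
})

test_that("identical seeds give bit-identical records", {
  p <- synth_params(seed = 42, duration_s = 1200)
  r1 <- generate_subject(p)
  r2 <- generate_subject(p)
  expect_identical(r1$v$value, r2$v$value)
  expect_identical(r1$hr$value, r2$hr$value)
  expect_identical(r1$scl$value, r2$scl$value)
  expect_identical(r1$v$mask, r2$v$mask)

  r3 <- generate_subject(synth_params(seed = 43, duration_s = 1200))
  expect_false(identical(r1$hr$value, r3$hr$value))
})

test_that("quantised vigilance stays on the 7-point scale", {
  for (seed in 1:4) {
    rec <- generate_subject(synth_params(seed = seed, duration_s = 1500))
    expect_true(all(rec$v$value %in% 1:7))
    mv <- mean(rec$v$value)
    expect_gte(mv, 1)
    expect_lte(mv, 7)
  }
})

test_that("the SCL step response is first order with the configured time constant", {
  tau <- 50
  # drive the filter with a step and fit the relaxation
  p <- synth_params(seed = 1, duration_s = 1000, scl_time_constant_s = tau,
                    noise_sd_scl = 0, scl_meas_noise_us = 0, noise_sd_v = 0,
                    drift_per_hr = 0, amp_mod_depth = 0, coupling_gain_scl = 0)
  # with zero gain the SCL drive is the constant baseline: response constant
  rec <- generate_subject(p)
  expect_lt(diff(range(rec$scl$value)), 1e-9)

  # explicit step through the same discrete filter
  alpha <- 1 - exp(-1 / tau)
  x <- c(rep(0, 10), rep(1, 400))
  y <- as.numeric(stats::filter(alpha * x, 1 - alpha,
                                method = "recursive", init = 0))
  expect_true(all(diff(y) >= -1e-12))      # monotone step response
  t63 <- which(y >= 1 - exp(-1))[1] - 10   # time to 63% of the step
  expect_lt(abs(t63 - tau) / tau, 0.05)
})

test_that("artifact fraction and falling-asleep counts are stored", {
  p <- synth_params(seed = 9, artifact_fraction = 0.1, duration_s = 2000)
  rec <- generate_subject(p)
  expect_equal(sum(rec$v$mask), round(0.1 * 2000))
  expect_identical(rec$v$mask, rec$hr$mask)
  expect_identical(rec$v$mask, rec$scl$mask)
  expect_gte(rec$falling_asleep_count, 0)
})

test_that("parameter validation rejects out-of-contract settings", {
  expect_error(synth_params(duration_s = 300, v_period_s = 190), "twice")
  expect_error(synth_params(delay_hr_s = 150), "100 s")
  expect_error(synth_params(artifact_fraction = 0.7), "0.5")
  expect_error(erp_synth_params(p_deviant = 1.2), "0, 1")
  expect_error(erp_synth_params(n1_latency_ms = 900), "epoch span")
})

test_that("zero coupling gains leave no recoverable coupling", {
  cmax <- sapply(1:6, function(seed) {
    p <- recovery_params(10, seed = seed, coupling_gain_hr = 0,
                         coupling_gain_scl = 0)
    run_subject(generate_subject(p))$coupling$c_max
  })
  expect_lt(median(cmax), 0.1)
})

test_that("the latent arousal period is recovered by the fluctuation stage", {
  p <- synth_params(v_period_s = 190, noise_sd_v = 0.3, ou_tau_s = 20,
                    drift_per_hr = 0, duration_s = 7200, seed = 7)
  a <- generate_latent_arousal(p)
  fl <- fluctuation_period(a, 170)
  expect_lt(abs(fl$median_period_s - 190) / 190, 0.10)
})

test_that("cohort generation derives subject seeds deterministically", {
  co1 <- generate_cohort(3, synth_params(duration_s = 1200), seed = 5)
  co2 <- generate_cohort(3, synth_params(duration_s = 1200), seed = 5)
  expect_identical(co1[[2]]$hr$value, co2[[2]]$hr$value)
  expect_false(identical(co1[[1]]$hr$value, co1[[2]]$hr$value))
  expect_equal(co1[[3]]$subject_id, "S03")

  varied <- generate_cohort(3, synth_params(duration_s = 1200), seed = 5,
                            vary = function(i) list(delay_hr_s = i * 10))
  expect_equal(varied[[2]]$params$delay_hr_s, 20)
})

test_that("oddball streams respect probabilities, ISIs and templates", {
  v <- uniform_series(rep(6, 7200), label = "V")
  ep <- erp_synth_params(n_stimuli = 5000, noise_sd_uv = 0, channels = "Fz",
                         vigilance_modulation = rep(1, 7), seed = 3)
  stream <- generate_erp_stream(ep, v)
  expect_equal(nrow(stream), 5000)

  # deviant count within binomial 3 sigma of 1000
  n_dev <- sum(stream$stimulus_type == "deviant")
  expect_lt(abs(n_dev - 1000), 3 * sqrt(5000 * 0.2 * 0.8))

  # ISIs uniform on [900, 1400] ms
  isi <- diff(stream$onset_s) * 1000
  expect_gte(min(isi), 900 - 1e-6)
  expect_lte(max(isi), 1400 + 1e-6)

  # follows_deviant marks exactly the successors of deviants
  expect_equal(stream$follows_deviant[-1],
               stream$stimulus_type[-5000] == "deviant")

  # noiseless, modulation 1: every epoch equals the template
  tmpl <- erp_template(ep)
  expect_equal(stream$samples[[17]], tmpl, tolerance = 1e-12)

  # planted -5 uV peak at 100 ms is recovered exactly by the ERP chain
  avg <- baseline_and_average(select_epochs(stream[stream$stimulus_type == "standard", ]))
  pk <- detect_peaks(avg)
  expect_equal(pk$n1_lat_ms, 100)
})

test_that("vigilance modulation scales epochs by the stage at onset", {
  v <- uniform_series(rep(c(6, 2), each = 1800), label = "V")
  mod <- c(0.2, 0.2, 0.2, 0.2, 0.2, 1, 1)
  ep <- erp_synth_params(n_stimuli = 3000, noise_sd_uv = 0, channels = "Cz",
                         vigilance_modulation = mod, seed = 11)
  stream <- generate_erp_stream(ep, v)
  tmpl <- erp_template(ep)
  early <- stream[stream$stage == 6, ]
  late <- stream[stream$stage == 2, ]
  expect_equal(early$samples[[1]], tmpl, tolerance = 1e-12)
  expect_equal(late$samples[[1]], 0.2 * tmpl, tolerance = 1e-12)

  # stage-restricted averages recover the stage-specific template scale
  pk6 <- detect_peaks(baseline_and_average(select_epochs(early)))
  pk2 <- detect_peaks(baseline_and_average(select_epochs(late)))
  expect_equal(pk2$p2_amp_uv / pk6$p2_amp_uv, 0.2, tolerance = 1e-9)
})
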