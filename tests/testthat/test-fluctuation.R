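test_that("tent kernel weights follow the triangular formula and sum to 1", {
  expect_equal(tent_kernel(3)$weights, c(0.25, 0.5, 0.25))

  # n = 5: w = (1 - |k-2|/3) / sum = c(1,2,3,2,1)/9
  expect_equal(tent_kernel(5)$weights, c(1, 2, 3, 2, 1) / 9)

  for (w in c(10, 57, 170)) {
    k <- tent_kernel(w)
    expect_equal(sum(k$weights), 1, tolerance = 1e-12)
    expect_equal(k$weights, rev(k$weights))           # symmetric
    expect_equal(length(k$weights) %% 2, 1)           # odd (zero phase)
    expect_true(all(diff(k$weights[1:(ceiling(length(k$weights) / 2))]) > 0))
  }
  expect_error(tent_kernel(2), "at least 3")
})

test_that("tent filtering preserves constants and matches a loop oracle", {
  expect_equal(filter_tent(rep(5, 100), tent_kernel(11)), rep(5, 100))

  set.seed(61)
  x <- rnorm(200)
  k <- tent_kernel(15)
  out <- filter_tent(x, k)
  h <- (length(k$weights) - 1) / 2
  for (i in (h + 1):(200 - h)) {
    expect_equal(out[i], sum(k$weights * x[(i - h):(i + h)]), tolerance = 1e-12)
  }
})

test_that("tent filtering attenuates a sinusoid without phase shift", {
  p <- 60
  x <- sinusoid_series(p, 600)
  out <- filter_tent(x, tent_kernel(21))
  # zero-phase: extrema of the filtered signal align with the input's
  interior <- 50:550
  ratio <- out[interior] / x[interior]
  ratio <- ratio[abs(x[interior]) > 0.3]
  expect_lt(diff(range(ratio)), 0.01)     # uniform attenuation, no distortion
  expect_true(all(ratio > 0 & ratio < 1))
})

test_that("cycle detection returns alternating extrema and handles plateaus", {
  ext <- find_cycles(c(0, 1, 0, 1, 0))
  expect_equal(ext$maxima_idx, c(2, 4))
  expect_equal(ext$minima_idx, 3)

  flat <- find_cycles(rep(2, 10))
  expect_length(flat$maxima_idx, 0)
  expect_length(flat$minima_idx, 0)

  # plateau maximum collapses to its centre sample
  ext2 <- find_cycles(c(0, 1, 2, 2, 2, 1, 0))
  expect_equal(ext2$maxima_idx, 4)

  # alternation property on noisy sinusoids
  for (seed in 1:3) {
    set.seed(seed)
    x <- filter_tent(sinusoid_series(50, 800) + rnorm(800, 0, 0.3),
                     tent_kernel(11))
    ext3 <- find_cycles(x)
    all_ext <- sort(c(ext3$maxima_idx, ext3$minima_idx))
    types <- ifelse(all_ext %in% ext3$maxima_idx, "M", "m")
    expect_true(all(types[-1] != types[-length(types)]))
  }
})

test_that("cycle amplitudes average the rises to both flanking minima", {
  # maximum of 3 with flanking minima 1 and 2 -> ((3-1)+(3-2))/2 = 1.5
  x <- c(2, 1, 3, 2, 4, 0, 1)
  ext <- find_cycles(x)
  amp <- cycle_amplitudes(x, ext$maxima_idx, ext$minima_idx)
  expect_equal(amp$max_idx, c(3L, 5L))
  expect_equal(amp$amplitude, c(1.5, ((4 - 2) + (4 - 0)) / 2))

  # a maximum before any minimum gets no amplitude (boundary rule)
  y <- c(0, 2, 1, 3, 0, 1)
  exty <- find_cycles(y)
  ampy <- cycle_amplitudes(y, exty$maxima_idx, exty$minima_idx)
  expect_false(2L %in% ampy$max_idx)
})

test_that("fluctuation period recovers sinusoid periods across widths", {
  for (p in c(40, 90, 150, 190, 260)) {
    for (nf in c(10, 50, 90, 170)) {
      if (nf > 0.8 * p) next
      fl <- fluctuation_period(sinusoid_series(p, 7200), nf)
      expect_lt(abs(fl$median_period_s - p), 2,
                label = sprintf("period %d, width %d", p, nf))
    }
  }
})

test_that("amplitude retention keeps cycles above the median amplitude", {
  # amplitude-modulated oscillation: cycle amplitudes vary, so the
  # median splits the cycles and only the stronger half is retained
  t <- 0:4799
  x <- (1 + 0.8 * sin(2 * pi * t / 1200)) * sin(2 * pi * t / 60)
  fl <- fluctuation_period(x, width_s = 11)
  med <- median(fl$cycles$amplitude)
  tol <- 1e-9 * max(fl$cycles$amplitude)
  expect_equal(fl$cycles$retained, fl$cycles$amplitude > med - tol)
  expect_gt(fl$n_retained, 1)
  expect_lt(fl$n_retained, fl$n_cycles)

  # with an even cycle count the median is the midpoint of the two
  # central amplitudes, so exactly half the cycles survive
  if (fl$n_cycles %% 2 == 0) {
    expect_equal(fl$n_retained, fl$n_cycles / 2)
  }

  # a pure sinusoid has all-equal amplitudes: every cycle is kept and
  # the period is the true one, not a multiple of it
  pure <- fluctuation_period(sinusoid_series(60, 4800), width_s = 11)
  expect_equal(pure$n_retained, pure$n_cycles)
})

test_that("filter width selects the described time scale in a two-scale signal", {
  x <- sinusoid_series(40, 7200) + sinusoid_series(200, 7200, amplitude = 1.5)
  fast <- fluctuation_period(x, 10)
  slow <- fluctuation_period(x, 170)
  expect_lt(abs(fast$median_period_s - 40), 4)
  expect_lt(abs(slow$median_period_s - 200), 4)
})

test_that("the estimator is invariant to affine transforms of the input", {
  set.seed(71)
  x <- sinusoid_series(100, 4000) + rnorm(4000, 0, 0.2)
  a <- glance(fluctuation_period(x, 50))
  b <- glance(fluctuation_period(5 * x + 20, 50))
  expect_equal(a$median_period_s, b$median_period_s)
  expect_equal(a$n_retained, b$n_retained)
})

test_that("wider filters do not increase the maxima count on a fixed signal", {
  # strict monotonicity on a clean oscillation
  clean <- sinusoid_series(150, 5000)
  clean_counts <- sapply(seq(10, 110, 20), function(nf) {
    length(find_cycles(filter_tent(clean, tent_kernel(nf)))$maxima_idx)
  })
  expect_true(all(diff(clean_counts) <= 0))

  # on noisy signals the count decreases strongly with width; the
  # alternation repair can shift a single extremum pair across a width
  # step, so one-count blips are tolerated
  for (seed in c(3, 17)) {
    set.seed(seed)
    x <- sinusoid_series(150, 5000) + rnorm(5000, 0, 0.5)
    counts <- sapply(seq(10, 200, 20), function(nf) {
      length(find_cycles(filter_tent(x, tent_kernel(nf)))$maxima_idx)
    })
    expect_true(all(diff(counts) <= 1))
    expect_lt(counts[length(counts)], counts[1] / 5)
  }
})

test_that("period estimates above the validity bound are flagged, not dropped", {
  x <- sinusoid_series(400, 7200)
  fl <- fluctuation_period(x, 170, validity_bound_s = 300)
  expect_false(fl$valid)
  expect_lt(abs(fl$median_period_s - 400), 2)
})

test_that("the inert synthetic SCL yields a much longer period than HR", {
  p <- synth_params(seed = 5)
  rec <- generate_subject(p)
  hr <- fill_missing(rec$hr)
  scl <- fill_missing(rec$scl)
  fl_hr <- fluctuation_period(hr, 90)
  fl_scl <- fluctuation_period(scl, 90)
  expect_gt(fl_scl$median_period_s / fl_hr$median_period_s, 1.5)
})

test_that("scan_filter_widths reports per-width correlations and exclusions", {
  set.seed(81)
  periods <- seq(80, 255, 25)
  t <- 0:3999
  series <- lapply(periods, function(p) {
    (1 + 0.6 * sin(2 * pi * t / 1300)) * sin(2 * pi * t / p) +
      rnorm(4000, 0, 0.05)
  })
  # "cmax" equal to the true periods themselves -> strong positive
  # correlation wherever every subject's period resolves
  scan <- scan_filter_widths(series, periods, widths_s = c(30, 50),
                             validity_bound_s = 300)
  expect_true(all(scan$r > 0.9))
  expect_true(all(scan$p < 1e-3))
  expect_equal(scan$n_valid, c(8, 8))

  expect_error(scan_filter_widths(series[1:3], periods[1:3]), "at least 4")
})
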