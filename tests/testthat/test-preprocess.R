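test_that("artifact propagation ORs the EEG mask into autonomic channels", {
  n <- 50
  set.seed(11)
  hr <- uniform_series(rnorm(n, 60), mask = runif(n) < 0.2, label = "HR")
  scl <- uniform_series(rnorm(n, 3), mask = runif(n) < 0.2, label = "SCL")
  eeg <- runif(n) < 0.3

  out <- propagate_artifacts(eeg, hr, scl)
  expect_equal(out$hr$mask, hr$mask | eeg)
  expect_equal(out$scl$mask, scl$mask | eeg)
  expect_equal(out$hr$value, hr$value)

  # all-false EEG mask leaves masks unchanged; a single mark propagates
  clean <- propagate_artifacts(rep(FALSE, n), hr, scl)
  expect_identical(clean$hr$mask, hr$mask)
  one <- rep(FALSE, n)
  one[6] <- TRUE
  hit <- propagate_artifacts(one, hr, scl)
  expect_true(hit$hr$mask[6])
  expect_true(hit$scl$mask[6])

  expect_error(propagate_artifacts(eeg[-1], hr, scl), "equal length")
})

test_that("hr_from_rr matches the closed form on constant interval streams", {
  rr <- rr_series(rep(1000, 120))
  hr <- hr_from_rr(rr)
  expect_true(all(abs(hr$value[!hr$mask] - 60) < 1e-12))

  rr8 <- rr_series(rep(800, 150))
  hr8 <- hr_from_rr(rr8)
  expect_true(all(abs(hr8$value[!hr8$mask] - 75) < 1e-12))
})

test_that("hr_from_rr equals a direct 3-window loop oracle on a mixed stream", {
  set.seed(21)
  rr_ms <- round(runif(160, 700, 1100))
  rr <- rr_series(rr_ms)
  hr <- hr_from_rr(rr)

  # oracle: per-second mean interval, then sliding centered 3-window
  n <- nrow(hr)
  seg_mean <- rep(NA_real_, n)
  for (s in 0:(n - 1)) {
    in_seg <- rr$time_s == s
    if (any(in_seg)) seg_mean[s + 1] <- mean(rr$rr_ms[in_seg])
  }
  for (tix in seq_len(n)) {
    w <- tix + (-1:1)
    if (tix == 1) w <- 1:3
    if (tix == n) w <- (n - 2):n
    if (all(w >= 1 & w <= n) && !any(is.na(seg_mean[w]))) {
      expect_equal(hr$value[tix], 60000 / mean(seg_mean[w]), tolerance = 1e-12)
      expect_false(hr$mask[tix])
    } else {
      expect_true(hr$mask[tix])
    }
  }
})

test_that("hr_from_rr masks 3-windows touching artifact segments and is shift-invariant", {
  rr_ms <- rep(1000, 60)
  art <- rep(FALSE, 60)
  art[30] <- TRUE
  hr <- hr_from_rr(rr_series(rr_ms), segment_artifact = art)
  expect_true(all(hr$mask[29:31]))
  expect_false(hr$mask[27])
  expect_false(hr$mask[33])

  # uniform time shift of the stream shifts the output, values unchanged
  set.seed(5)
  rr_ms <- round(runif(80, 800, 1000))
  base <- hr_from_rr(rr_series(rr_ms, t0_s = 0))
  shifted <- hr_from_rr(rr_series(rr_ms, t0_s = 10))
  # interior values shift with the stream (edges use the boundary window)
  expect_equal(shifted$value[12:nrow(base)], base$value[2:(nrow(base) - 10)],
               tolerance = 1e-12)

  expect_warning(
    hr_from_rr(rr_series(rep(1000, 10)), segment_artifact = rep(TRUE, 10)),
    "fully masked"
  )
})

test_that("scl_per_segment averages each second of 100 Hz samples", {
  expect_equal(scl_per_segment(rep(3.5, 500))$value, rep(3.5, 5))
  expect_equal(scl_per_segment(1:100)$value, 50.5)

  set.seed(31)
  x <- rnorm(700, 3, 0.5)
  out <- scl_per_segment(x)
  oracle <- sapply(1:7, function(s) mean(x[((s - 1) * 100 + 1):(s * 100)]))
  expect_equal(out$value, oracle, tolerance = 1e-12)

  expect_message(scl_per_segment(rnorm(250)), "trailing")
  expect_equal(nrow(suppressMessages(scl_per_segment(rnorm(250)))), 2)
})

test_that("fill_missing imputes the subject mean and preserves unmasked values", {
  s <- uniform_series(c(1, NA, 3), label = "V")
  filled <- fill_missing(s)
  expect_equal(filled$value, c(1, 2, 3))
  expect_false(any(filled$mask))

  # identity on a gap-free series
  clean <- uniform_series(c(4, 5, 6))
  expect_equal(fill_missing(clean)$value, clean$value)

  # conservation: imputation leaves the unmasked mean untouched
  set.seed(41)
  v <- rnorm(500, 4)
  m <- runif(500) < 0.1
  out <- fill_missing(uniform_series(v, mask = m))
  expect_equal(mean(out$value), mean(v[!m]), tolerance = 1e-12)
  expect_equal(out$value[!m], v[!m])

  expect_error(fill_missing(uniform_series(c(1, 2), mask = TRUE)), "fully masked")
})

test_that("zscore standardises to population moments and is affine invariant", {
  z <- zscore(uniform_series(c(1, 2, 3)))
  expect_equal(mean(z$value), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z$value^2)), 1, tolerance = 1e-12)

  set.seed(51)
  x <- rnorm(300)
  expect_equal(zscore(3.2 * x - 7), zscore(x), tolerance = 1e-12)

  z2 <- zscore(rnorm(1000))
  expect_lt(abs(mean(z2)), 1e-12)
  expect_lt(abs(sqrt(mean(z2^2)) - 1), 1e-12)

  expect_error(zscore(rep(2, 10)), "constant")
})
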