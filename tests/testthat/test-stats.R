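test_that("Pearson correlation matches base R and handles exact relations", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.7, 2.9)
  expect_equal(cor_pearson(x, 2 * x + 3)$estimate, 1)
  expect_equal(cor_pearson(c(1, 2, 3, 4), c(4, 3, 2, 1))$estimate, -1)

  set.seed(91)
  a <- rnorm(39)
  b <- rnorm(39)
  res <- cor_pearson(a, b)
  ref <- cor.test(a, b)
  expect_equal(res$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$p_two_tailed, ref$p.value, tolerance = 1e-12)
  expect_error(cor_pearson(a, rep(1, 39)), "Constant")
})

test_that("Spearman equals Pearson-on-midranks and is monotone invariant", {
  set.seed(92)
  x <- rnorm(30)
  expect_equal(cor_spearman(x, exp(x))$estimate, 1)
  expect_equal(cor_spearman(x, -x^3)$estimate, -1)

  y <- rnorm(30)
  x[5] <- x[9]  # introduce ties to exercise midranks
  res <- cor_spearman(x, y)
  expect_equal(res$estimate, cor(rank(x), rank(y)), tolerance = 1e-12)
  ref <- cor.test(rank(x), rank(y), method = "pearson")
  expect_equal(res$p_two_tailed, ref$p.value, tolerance = 1e-12)
})

test_that("Welch t from summaries equals Welch t from raw vectors and base R", {
  set.seed(93)
  x1 <- rnorm(19, 10, 4)
  x2 <- rnorm(20, 8, 1.5)
  raw <- welch_t(x1, x2)
  summ <- welch_t(m1 = mean(x1), s1 = sd(x1), n1 = 19,
                  m2 = mean(x2), s2 = sd(x2), n2 = 20)
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
  expect_equal(raw$df, summ$df, tolerance = 1e-12)
  expect_equal(raw$p_two_tailed, summ$p_two_tailed, tolerance = 1e-12)

  ref <- t.test(x1, x2, var.equal = FALSE)
  expect_equal(raw$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(raw$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(raw$p_two_tailed, ref$p.value, tolerance = 1e-12)

  # equal means -> t = 0; equal variances and n -> df = n1 + n2 - 2
  expect_equal(welch_t(m1 = 5, s1 = 2, n1 = 10, m2 = 5, s2 = 3, n2 = 12)$statistic, 0)
  expect_equal(welch_t(m1 = 1, s1 = 2, n1 = 15, m2 = 2, s2 = 2, n2 = 15)$df, 28)
})

test_that("Student t matches the pooled formula and base R", {
  x1 <- c(3.1, 4.5, 2.2)
  x2 <- c(5.0, 6.1, 4.4)
  res <- student_t(x1, x2)
  sp2 <- (2 * var(x1) + 2 * var(x2)) / 4
  t_hand <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  ref <- t.test(x1, x2, var.equal = TRUE)
  expect_equal(res$p_two_tailed, ref$p.value, tolerance = 1e-12)

  same <- student_t(x1, x1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_two_tailed, 1)
})

test_that("Cohen's d uses the pooled-SD convention", {
  expect_equal(cohens_d(m1 = 0, s1 = 1, n1 = 10, m2 = 1, s2 = 1, n2 = 10), 1)
  expect_equal(cohens_d(m1 = 4, s1 = 2, n1 = 8, m2 = 4, s2 = 3, n2 = 9), 0)
  # worked example from a published latency row: 186.79 (31.87) n=19 vs
  # 189.50 (20.91) n=20 -> d = 0.101
  d <- cohens_d(m1 = 186.79, s1 = 31.87, n1 = 19,
                m2 = 189.50, s2 = 20.91, n2 = 20)
  expect_equal(round(d, 3), 0.101)
})

test_that("chi-square on 2x2 tables matches the closed form without correction", {
  # gender split 9/10 vs 13/7 -> chi2 = 1.232, p = 0.267
  res <- chi2_2x2(9, 13, 10, 7)
  expect_equal(round(res$statistic, 3), 1.232)
  expect_equal(round(res$p_two_tailed, 3), 0.267)

  # proportional table -> chi2 = 0, p = 1
  prop <- chi2_2x2(10, 20, 5, 10)
  expect_equal(prop$statistic, 0, tolerance = 1e-12)
  expect_equal(prop$p_two_tailed, 1)

  # closed form n(ad - bc)^2 / product of margins
  for (tab in list(c(3, 8, 5, 2), c(12, 7, 9, 14))) {
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
    n <- sum(tab)
    hand <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(chi2_2x2(a, b, c, d)$statistic, hand, tolerance = 1e-12)
  }
  expect_error(chi2_2x2(0, 0, 3, 4), "margin")
})

test_that("Mann-Whitney U counts pairs and matches enumeration at n = 3", {
  res <- mann_whitney(c(1, 2, 3), c(10, 20, 30))
  expect_equal(res$estimate, 0)

  # exhaustive enumeration oracle for U on all arrangements
  x1 <- c(1.3, 5.2, 2.8)
  x2 <- c(2.1, 0.4, 6.6)
  u_brute <- sum(outer(x1, x2, ">")) + 0.5 * sum(outer(x1, x2, "=="))
  expect_equal(mann_whitney(x1, x2)$estimate, u_brute)

  # tie-corrected normal approximation agrees with base R's wilcox.test
  set.seed(94)
  a <- sample(1:8, 20, replace = TRUE)
  b <- sample(2:9, 22, replace = TRUE)
  res2 <- mann_whitney(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  expect_equal(res2$estimate, unname(ref$statistic))
  expect_equal(res2$p_two_tailed, ref$p.value, tolerance = 1e-10)
})

test_that("the Levene gate selects Welch under variance heterogeneity", {
  set.seed(95)
  x1 <- rnorm(40, 0, 1)
  x2 <- rnorm(40, 0, 6)
  res <- compare_groups(x1, x2)
  expect_equal(res$method[res$selected], "welch_t")

  y2 <- rnorm(40, 0.5, 1)
  res2 <- compare_groups(x1, y2)
  expect_equal(res2$method[res2$selected], "student_t")
  # both tests are always present for transparency
  expect_setequal(res2$method, c("student_t", "welch_t", "levene"))
})

test_that("published summary tables recompute to their printed statistics", {
  erp <- recompute_group_stats(published_erp_group_stats())
  cons <- erp[erp$t_consistent == 1, ]
  expect_gte(nrow(cons), 5)
  expect_true(all(abs(cons$t_computed - cons$t_printed) <= 0.03))
  wl <- cons[cons$test == "welch", ]
  expect_true(all(abs(wl$df_computed - wl$df_printed) <= 0.15))
  d_ok <- erp[erp$d_consistent == 1, ]
  expect_true(all(abs(d_ok$d_computed - d_ok$d_printed) <= 0.012))
})
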