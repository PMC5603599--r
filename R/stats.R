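#' Tidy statistical-test results
#'
#' All test helpers in the package return a one-row tibble of class
#' `stat_result` with columns `method`, `estimate` (correlation
#' coefficient, mean difference, or U), `statistic`, `df` (possibly
#' non-integer; `NA` where not applicable), `p_two_tailed`, `effect_size`
#' (Cohen's d for two-sample tests, r/rho for correlations), `n1`, `n2`.
#' All tests are two-tailed.
#'
#' @name stat_result
NULL

stat_result <- function(method, estimate, statistic, df, p, effect_size,
                        n1, n2 = NA_integer_) {
  out <- tibble(
    method = method,
    estimate = estimate,
    statistic = statistic,
    df = df,
    p_two_tailed = p,
    effect_size = effect_size,
    n1 = as.integer(n1),
    n2 = as.integer(n2)
  )
  class(out) <- c("stat_result", class(out))
  out
}

#' Pearson product-moment correlation
#'
#' Correlation coefficient with a two-tailed p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors, equal length n >= 4, non-constant.
#' @return A [stat_result] row (`estimate` and `effect_size` are r).
#' @export
cor_pearson <- function(x, y) {
  check_cor_input(x, y)
  n <- length(x)
  r <- cor(x, y)
  p <- cor_t_p(r, n)
  stat_result("pearson", r, cor_t_stat(r, n), n - 2, p, r, n)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with a two-tailed p-value via the
#' same t approximation as [cor_pearson()] (appropriate for the sample
#' sizes this package targets; exact tie handling via midranks).
#'
#' @inheritParams cor_pearson
#' @return A [stat_result] row (`estimate` and `effect_size` are rho).
#' @export
cor_spearman <- function(x, y) {
  check_cor_input(x, y)
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  if (pop_sd(rx) == 0 || pop_sd(ry) == 0) abort("Constant ranks; rho undefined.")
  rho <- cor(rx, ry)
  stat_result("spearman", rho, cor_t_stat(rho, n), n - 2, cor_t_p(rho, n), rho, n)
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 4) abort("Need at least 4 observations.")
  if (anyNA(x) || anyNA(y)) abort("Missing values not allowed; filter first.")
  if (pop_sd(x) == 0 || pop_sd(y) == 0) abort("Constant input; correlation undefined.")
  invisible(TRUE)
}

cor_t_stat <- function(r, n) {
  if (abs(r) >= 1) return(sign(r) * Inf)
  r * sqrt((n - 2) / (1 - r^2))
}

cor_t_p <- function(r, n) {
  t <- cor_t_stat(r, n)
  if (is.infinite(t)) return(0)
  2 * pt(-abs(t), df = n - 2)
}

#' Welch's unequal-variance t-test
#'
#' Two-sample t-test with the Welch-Satterthwaite degrees of freedom
#' \deqn{df = (s_1^2/n_1 + s_2^2/n_2)^2 /
#'   [ (s_1^2/n_1)^2/(n_1-1) + (s_2^2/n_2)^2/(n_2-1) ].}
#' Accepts either two raw vectors (`x1`, `x2`) or the printed summaries
#' (`m`, `s`, `n` per group), so published group tables can be
#' re-examined without the raw data. Sample (1/(n-1)) standard
#' deviations are expected.
#'
#' @param x1,x2 Raw samples (ignored when summaries are given).
#' @param m1,s1,n1,m2,s2,n2 Group means, SDs and sizes.
#' @return A [stat_result] row; `estimate` is `m1 - m2`, `effect_size`
#'   pooled-SD Cohen's d.
#' @export
#' @examples
#' welch_t(m1 = 186.79, s1 = 31.87, n1 = 19,
#'         m2 = 189.50, s2 = 20.91, n2 = 20)
welch_t <- function(x1 = NULL, x2 = NULL,
                    m1 = NULL, s1 = NULL, n1 = NULL,
                    m2 = NULL, s2 = NULL, n2 = NULL) {
  if (!is.null(x1)) {
    m1 <- mean(x1); s1 <- sd(x1); n1 <- length(x1)
  }
  if (!is.null(x2)) {
    m2 <- mean(x2); s2 <- sd(x2); n2 <- length(x2)
  }
  if (n1 < 2 || n2 < 2) abort("Both groups need n >= 2.")
  if (s1 == 0 && s2 == 0) abort("Zero variance in both groups.")
  a <- s1^2 / n1
  b <- s2^2 / n2
  t <- (m1 - m2) / sqrt(a + b)
  df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df = df)
  stat_result("welch_t", m1 - m2, t, df, p,
              cohens_d(m1 = m1, s1 = s1, n1 = n1, m2 = m2, s2 = s2, n2 = n2),
              n1, n2)
}

#' Student's pooled-variance t-test
#'
#' Independent two-sample t-test with pooled variance and
#' `df = n1 + n2 - 2`. Accepts raw vectors or group summaries like
#' [welch_t()].
#'
#' @inheritParams welch_t
#' @return A [stat_result] row.
#' @export
student_t <- function(x1 = NULL, x2 = NULL,
                      m1 = NULL, s1 = NULL, n1 = NULL,
                      m2 = NULL, s2 = NULL, n2 = NULL) {
  if (!is.null(x1)) {
    m1 <- mean(x1); s1 <- sd(x1); n1 <- length(x1)
  }
  if (!is.null(x2)) {
    m2 <- mean(x2); s2 <- sd(x2); n2 <- length(x2)
  }
  if (n1 < 2 || n2 < 2) abort("Both groups need n >= 2.")
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) abort("Zero pooled variance.")
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- 2 * pt(-abs(t), df = df)
  stat_result("student_t", m1 - m2, t, df, p,
              cohens_d(m1 = m1, s1 = s1, n1 = n1, m2 = m2, s2 = s2, n2 = n2),
              n1, n2)
}

#' Cohen's d (pooled-SD convention)
#'
#' `d = |m1 - m2| / s_pooled` with
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' Accepts raw vectors or group summaries.
#'
#' @inheritParams welch_t
#' @return A single non-negative number.
#' @export
cohens_d <- function(x1 = NULL, x2 = NULL,
                     m1 = NULL, s1 = NULL, n1 = NULL,
                     m2 = NULL, s2 = NULL, n2 = NULL) {
  if (!is.null(x1)) {
    m1 <- mean(x1); s1 <- sd(x1); n1 <- length(x1)
  }
  if (!is.null(x2)) {
    m2 <- mean(x2); s2 <- sd(x2); n2 <- length(x2)
  }
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) abort("Zero pooled SD; d undefined.")
  abs(m1 - m2) / sp
}

#' Chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction (df = 1), matching
#' the convention in which a 19-vs-20 gender split of 9/10 vs 13/7 gives
#' chi-square 1.232, p = 0.267.
#'
#' @param a,b First row of counts (e.g. females in groups 1 and 2).
#' @param c,d Second row of counts.
#' @return A [stat_result] row; `effect_size` is the phi coefficient.
#' @export
chi2_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) abort("Counts must be non-negative.")
  n <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) abort("Empty table margin; chi-square undefined.")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  phi <- sqrt(unname(ct$statistic) / n)
  stat_result("chi2", phi, unname(ct$statistic), unname(ct$parameter),
              ct$p.value, phi, a + b, c + d)
}

#' Mann-Whitney U test
#'
#' Rank-sum test for two independent samples. Reports the U statistic
#' (number of (x1, x2) pairs with x1 > x2, counting ties as 1/2) and a
#' two-tailed p from the tie-corrected normal approximation.
#'
#' @param x1,x2 Numeric samples.
#' @return A [stat_result] row; `estimate` is U, `effect_size` the
#'   rank-biserial correlation `1 - 2U/(n1 n2)`.
#' @export
mann_whitney <- function(x1, x2) {
  n1 <- length(x1)
  n2 <- length(x2)
  if (n1 < 1 || n2 < 1) abort("Both samples must be non-empty.")
  r <- rank(c(x1, x2))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nt <- n1 + n2
  ties <- table(c(x1, x2))
  tie_term <- sum(ties^3 - ties) / (nt * (nt - 1))
  sigma2 <- n1 * n2 / 12 * (nt + 1 - tie_term)
  if (sigma2 <= 0) {
    p <- 1
    z <- 0
  } else {
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    p <- min(p, 1)
  }
  stat_result("mannwhitney", u, z, NA_real_, p, 1 - 2 * u / (n1 * n2), n1, n2)
}

#' Two-group Levene/Brown-Forsythe variance-homogeneity check
#'
#' t-test on absolute deviations from each group's centre (mean by
#' default; `center = median` gives the Brown-Forsythe variant). Used as
#' the gate between [student_t()] and [welch_t()] in group comparisons.
#'
#' @param x1,x2 Numeric samples.
#' @param center Function computing the group centre.
#' @return A [stat_result] row; small p means heterogeneous variances.
#' @export
levene_2g <- function(x1, x2, center = mean) {
  d1 <- abs(x1 - center(x1))
  d2 <- abs(x2 - center(x2))
  tt <- t.test(d1, d2, var.equal = TRUE)
  stat_result("levene", mean(d1) - mean(d2), unname(tt$statistic),
              unname(tt$parameter), tt$p.value, NA_real_,
              length(x1), length(x2))
}

#' Two-group comparison with an automatic test-selection protocol
#'
#' Computes both Student and Welch t-tests and selects per protocol:
#' Welch when the Levene check rejects variance homogeneity at
#' `alpha = 0.05`, Student otherwise. Both results are returned so the
#' choice is transparent.
#'
#' @param x1,x2 Numeric samples.
#' @param alpha Significance level of the variance-homogeneity gate.
#' @return Tibble with the selected test first (column `selected`),
#'   stacked [stat_result] rows for `student_t`, `welch_t` and `levene`.
#' @export
compare_groups <- function(x1, x2, alpha = 0.05) {
  lev <- levene_2g(x1, x2)
  st <- student_t(x1, x2)
  wt <- welch_t(x1, x2)
  use_welch <- lev$p_two_tailed < alpha
  out <- dplyr::bind_rows(st, wt, lev)
  out$selected <- c(!use_welch, use_welch, FALSE)
  out[order(-out$selected), ]
}
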