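#' Published group-comparison summary tables
#'
#' The package ships the printed group summaries (means, SDs, group
#' sizes, and the published test statistics) of a 39-subject study
#' cohort split by coupling delay: general group characteristics, the
#' A1-restricted ERP (N1/P2) group comparison, and the gender counts.
#' They serve as worked examples for the summary-statistic tests: the
#' `test` column records whether the published degrees of freedom imply
#' a pooled (Student) or unequal-variance (Welch) test, and the
#' `t_consistent` / `d_consistent` flags in the ERP table mark rows
#' whose printed statistic is reproducible from the row's own printed
#' summaries (a few published rows are internally inconsistent,
#' apparently from row transpositions in the source table, and are
#' flagged 0).
#'
#' @return A tibble.
#' @export
published_group_characteristics <- function() {
  read_published("published_group_characteristics.tsv")
}

#' @rdname published_group_characteristics
#' @export
published_erp_group_stats <- function() {
  read_published("published_erp_group_stats.tsv")
}

#' @rdname published_group_characteristics
#' @export
published_gender_counts <- function() {
  read_published("published_gender_counts.tsv")
}

read_published <- function(name) {
  path <- system.file("extdata", name, package = "vigicouple")
  if (path == "") abort(sprintf("Fixture %s not found.", name))
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                  na = "NA")
}

#' Recompute test statistics from printed group summaries
#'
#' Applies [student_t()], [welch_t()] and [cohens_d()] to each row's
#' printed means/SDs/group sizes and reports both computed tests plus
#' the one selected by the row's `test` column, for side-by-side
#' comparison with the printed values.
#'
#' @param tbl A tibble with columns `mean_I`, `sd_I`, `n_I`, `mean_II`,
#'   `sd_II`, `n_II` and optionally `test`, e.g. from
#'   [published_erp_group_stats()].
#' @return The input with computed columns `t_student`, `p_student`,
#'   `t_welch`, `df_welch`, `p_welch`, `d_computed`, and (when `test`
#'   is present) `t_computed`, `df_computed`, `p_computed` for the
#'   selected test.
#' @export
recompute_group_stats <- function(tbl) {
  comp <- purrr::pmap_dfr(
    tbl[, c("mean_I", "sd_I", "n_I", "mean_II", "sd_II", "n_II")],
    function(mean_I, sd_I, n_I, mean_II, sd_II, n_II) {
      st <- student_t(m1 = mean_I, s1 = sd_I, n1 = n_I,
                      m2 = mean_II, s2 = sd_II, n2 = n_II)
      wt <- welch_t(m1 = mean_I, s1 = sd_I, n1 = n_I,
                    m2 = mean_II, s2 = sd_II, n2 = n_II)
      tibble(
        t_student = st$statistic, p_student = st$p_two_tailed,
        t_welch = wt$statistic, df_welch = wt$df, p_welch = wt$p_two_tailed,
        d_computed = st$effect_size
      )
    }
  )
  out <- dplyr::bind_cols(tbl, comp)
  if ("test" %in% names(tbl)) {
    sel_welch <- !is.na(tbl$test) & tbl$test == "welch"
    sel_student <- !is.na(tbl$test) & tbl$test == "student"
    out$t_computed <- dplyr::case_when(
      sel_welch ~ out$t_welch,
      sel_student ~ out$t_student,
      TRUE ~ NA_real_
    )
    out$df_computed <- dplyr::case_when(
      sel_welch ~ out$df_welch,
      sel_student ~ out$n_I + out$n_II - 2,
      TRUE ~ NA_real_
    )
    out$p_computed <- dplyr::case_when(
      sel_welch ~ out$p_welch,
      sel_student ~ out$p_student,
      TRUE ~ NA_real_
    )
  }
  out
}
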