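#' Analysis configuration defaults
#'
#' Collects the tunable settings of the per-subject pipeline: the
#' cross-correlation lag range, the tent-filter widths used for the
#' vigilance and heart-rate fluctuation periods (170 s and 90 s — the
#' widths at which cohort-level correlations with coupling strength
#' peak), the validity bound on period estimates, ERP search windows and
#' the stage score treated as relaxed wakefulness (A1 = 6) for the
#' arousal-controlled ERP analysis.
#'
#' @param max_lag_s Cross-correlation scan range, seconds.
#' @param width_v_s,width_hr_s Tent widths for V- and HR-derived
#'   periods.
#' @param validity_bound_s Longest credible fluctuation period.
#' @param erp_windows Peak search windows, ms (see [detect_peaks()]).
#' @param erp_halfwin_ms Amplitude half-windows, ms.
#' @param min_epochs Minimum epochs per ERP average.
#' @param a1_stage Stage score used for the A1 restriction.
#' @param peak_mode Cross-correlation peak rule (see
#'   [extract_coupling()]).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(max_lag_s = 100,
                            width_v_s = 170,
                            width_hr_s = 90,
                            validity_bound_s = 300,
                            erp_windows = list(n1 = c(70, 140), p2 = c(140, 260)),
                            erp_halfwin_ms = c(n1 = 10, p2 = 20),
                            min_epochs = 50,
                            a1_stage = 6,
                            peak_mode = "abs") {
  structure(as.list(environment()), class = "analysis_config")
}

#' Percentage of switches between main vigilance stage classes
#'
#' Stage scores map to the four main classes 0 (score 7), A (6, 5, 4),
#' B (3, 2) and C (1); the statistic is the percentage of
#' consecutive-second transitions on which the class changes.
#'
#' @param v A `uniform_series` of stage scores (or numeric vector).
#' @return Percentage in [0, 100].
#' @export
#' @examples
#' stage_switch_pct(c(6, 6, 5, 3, 3, 1))  # A A A B B C -> 40
stage_switch_pct <- function(v) {
  s <- if (is.data.frame(v)) v$value else as.numeric(v)
  if (length(s) < 2) abort("Need at least 2 seconds to count switches.")
  cls <- main_stage_class(s)
  100 * sum(cls[-1] != cls[-length(cls)]) / (length(cls) - 1)
}

main_stage_class <- function(score) {
  cut(score,
      breaks = c(0.5, 1.5, 3.5, 6.5, 7.5),
      labels = c("C", "B", "A", "0"))
}

#' Run the full analysis for one subject
#'
#' Executes preprocessing (artifact propagation, mean imputation,
#' normalisation), coupling (lagged cross-correlation, C_max / T_max /
#' group), fluctuation-period estimation at the configured widths, and —
#' when the record carries ERP epochs — peak extraction for all stages
#' and restricted to relaxed wakefulness (A1).
#'
#' A fully masked SCL channel is tolerated: coupling is then computed
#' from the heart-rate channel alone and the SCL fields are `NA`.
#'
#' @param record A `subject_record` (e.g. from [generate_subject()] or
#'   [read_subject_record()]).
#' @param config An [analysis_config()].
#' @return An object of class `subject_summary`; [tidy()] returns its
#'   one-row tibble form.
#' @export
run_subject <- function(record, config = analysis_config()) {
  with_subject_context(record$subject_id, {
    prop <- propagate_artifacts(record$v$mask, record$hr, record$scl)
    v <- fill_missing(record$v)
    hr <- fill_missing(prop$hr)
    scl_ok <- !all(prop$scl$mask)
    scl <- if (scl_ok) fill_missing(prop$scl) else NULL

    curve_vhr <- cross_correlate(zscore(v), zscore(hr), config$max_lag_s)
    curve_vscl <- if (scl_ok) {
      cross_correlate(zscore(v), zscore(scl), config$max_lag_s)
    } else {
      NULL
    }
    coupling <- extract_coupling(curve_vhr, curve_vscl, mode = config$peak_mode)

    fl_v <- try_fluctuation(v, config$width_v_s, config$validity_bound_s)
    fl_hr <- try_fluctuation(hr, config$width_hr_s, config$validity_bound_s)

    erp_all <- NULL
    erp_a1 <- NULL
    if (!is.null(record$epochs)) {
      erp_all <- erp_condition_peaks(
        record$epochs,
        windows = config$erp_windows, halfwin_ms = config$erp_halfwin_ms,
        min_epochs = config$min_epochs
      )
      erp_a1 <- erp_condition_peaks(
        record$epochs, stage_restriction = config$a1_stage,
        windows = config$erp_windows, halfwin_ms = config$erp_halfwin_ms,
        min_epochs = config$min_epochs
      )
    }

    structure(
      list(
        subject_id = record$subject_id,
        mean_vigilance_score = mean(record$v$value[!record$v$mask]),
        # switches counted on artifact-free seconds only: the continuous
        # imputed mean would otherwise fabricate class changes
        switch_pct_main_stages = stage_switch_pct(record$v$value[!record$v$mask]),
        falling_asleep_count = record$falling_asleep_count %||% NA_integer_,
        mean_hr_bpm = mean(hr$value),
        mean_scl_us = if (scl_ok) mean(scl$value) else NA_real_,
        coupling = coupling,
        fluctuation_v = fl_v,
        fluctuation_hr = fl_hr,
        erp_all = erp_all,
        erp_a1 = erp_a1
      ),
      class = "subject_summary"
    )
  })
}

with_subject_context <- function(subject_id, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      abort(
        sprintf("Subject %s: %s", subject_id, conditionMessage(e)),
        class = "vigicouple_subject_error",
        parent = e
      )
    }
  )
}

try_fluctuation <- function(series, width_s, bound_s) {
  tryCatch(
    fluctuation_period(series, width_s, validity_bound_s = bound_s),
    vigicouple_no_cycles = function(e) NULL
  )
}

#' @export
print.subject_summary <- function(x, ...) {
  cat(sprintf(
    "Subject %s: mean V %.2f, switches %.1f%%, C_max %.3f, T_max %.1f s (Group %s)\n",
    x$subject_id, x$mean_vigilance_score, x$switch_pct_main_stages,
    x$coupling$c_max, x$coupling$t_max_s, x$coupling$group
  ))
  invisible(x)
}

#' @export
tidy.subject_summary <- function(x, ...) {
  base <- tibble(
    subject_id = x$subject_id,
    mean_vigilance_score = x$mean_vigilance_score,
    switch_pct_main_stages = x$switch_pct_main_stages,
    falling_asleep_count = x$falling_asleep_count,
    mean_hr_bpm = x$mean_hr_bpm,
    mean_scl_us = x$mean_scl_us
  )
  cp <- tidy(x$coupling)
  fl <- tibble(
    period_v_s = if (is.null(x$fluctuation_v)) NA_real_ else x$fluctuation_v$median_period_s,
    period_v_valid = if (is.null(x$fluctuation_v)) NA else x$fluctuation_v$valid,
    period_hr_s = if (is.null(x$fluctuation_hr)) NA_real_ else x$fluctuation_hr$median_period_s,
    period_hr_valid = if (is.null(x$fluctuation_hr)) NA else x$fluctuation_hr$valid
  )
  out <- dplyr::bind_cols(base, cp, fl)
  if (!is.null(x$erp_all)) {
    out <- dplyr::bind_cols(out, widen_erp(x$erp_all, prefix = ""))
  }
  if (!is.null(x$erp_a1)) {
    out <- dplyr::bind_cols(out, widen_erp(x$erp_a1, prefix = "a1_"))
  }
  out
}

widen_erp <- function(peaks, prefix = "") {
  long <- tidyr::pivot_longer(
    peaks[, c("channel", "stimulus_type", "n1_amp_uv", "n1_lat_ms",
              "p2_amp_uv", "p2_lat_ms")],
    cols = c("n1_amp_uv", "n1_lat_ms", "p2_amp_uv", "p2_lat_ms"),
    names_to = "measure", values_to = "value"
  )
  long$name <- paste0(
    prefix, tolower(long$channel), "_",
    substr(long$stimulus_type, 1, 3), "_", long$measure
  )
  tidyr::pivot_wider(long[, c("name", "value")],
                     names_from = "name", values_from = "value")
}

#' Run the cohort-level analysis
#'
#' Analyses every subject with [run_subject()] and assembles the study's
#' three result sets: (a) correlations between coupling measures
#' (C_max, T_max) and the V-/HR-derived fluctuation periods, (b)
#' correlations between coupling/fluctuation measures and the ERP peak
#' measures plus the P2-vs-falling-asleep association, and (c)
#' group-comparison tables contrasting subjects with (Group I) and
#' without (Group II) a measurable coupling delay, including the
#' A1-restricted ERP control comparison.
#'
#' Pearson or Spearman correlation is chosen per pair by a Shapiro-Wilk
#' normality gate at alpha = 0.05 (Spearman when either variable
#' deviates from normality); both group t-tests are reported with the
#' Levene-gated selection flagged (see [compare_groups()]).
#'
#' @param records List of `subject_record`s (>= 4).
#' @param config An [analysis_config()].
#' @return An object of class `cohort_result`: list with `summaries`
#'   (one tidy row per subject), `coupling_fluctuation`, `erp_relations`
#'   and `group_comparison` tibbles.
#' @export
run_cohort <- function(records, config = analysis_config()) {
  if (length(records) < 4) abort("Need at least 4 subjects.")
  summaries_raw <- purrr::map(records, run_subject, config = config)
  summaries <- purrr::map_dfr(summaries_raw, tidy)

  h1 <- cohort_h1(summaries)
  h2 <- if (any(grepl("^fz_|^cz_", names(summaries)))) {
    cohort_h2(summaries)
  } else {
    NULL
  }
  groups <- cohort_group_comparison(summaries)

  structure(
    list(
      summaries = summaries,
      coupling_fluctuation = h1,
      erp_relations = h2,
      group_comparison = groups,
      config = config
    ),
    class = "cohort_result"
  )
}

# Shapiro-gated correlation between two cohort variables
gated_correlation <- function(x, y, alpha = 0.05) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 4 || pop_sd(x) == 0 || pop_sd(y) == 0) {
    return(stat_result("pearson", NA_real_, NA_real_, NA_real_, NA_real_,
                       NA_real_, length(x)))
  }
  normal <- function(v) {
    if (length(unique(v)) < 3) return(FALSE)
    shapiro.test(v)$p.value >= alpha
  }
  if (normal(x) && normal(y)) cor_pearson(x, y) else cor_spearman(x, y)
}

cohort_h1 <- function(s) {
  pairs <- tidyr::expand_grid(
    coupling = c("c_max", "t_max_s"),
    period = c("period_v_s", "period_hr_s")
  )
  purrr::pmap_dfr(pairs, function(coupling, period) {
    valid <- if (period == "period_v_s") s$period_v_valid else s$period_hr_valid
    keep <- !is.na(valid) & valid
    res <- gated_correlation(s[[coupling]][keep], s[[period]][keep])
    dplyr::bind_cols(tibble(x = coupling, y = period), res)
  })
}

cohort_h2 <- function(s) {
  erp_cols <- grep("^(fz|cz)_(sta|dev)_(n1|p2)_(amp_uv|lat_ms)$",
                   names(s), value = TRUE)
  pairs <- tidyr::expand_grid(
    x = c("t_max_s", "period_v_s", "period_hr_s"),
    y = erp_cols
  )
  main <- purrr::pmap_dfr(pairs, function(x, y) {
    dplyr::bind_cols(tibble(x = x, y = y), gated_correlation(s[[x]], s[[y]]))
  })
  a1_p2 <- grep("^a1_(fz|cz)_(sta|dev)_p2_amp_uv$", names(s), value = TRUE)
  asleep <- purrr::map_dfr(a1_p2, function(col) {
    dplyr::bind_cols(
      tibble(x = "falling_asleep_count", y = col),
      gated_correlation(s$falling_asleep_count, s[[col]])
    )
  })
  dplyr::bind_rows(main, asleep)
}

cohort_group_comparison <- function(s) {
  g1 <- s$group == "I"
  g2 <- s$group == "II"
  vars <- c(
    "mean_vigilance_score", "switch_pct_main_stages", "falling_asleep_count",
    "mean_hr_bpm", "mean_scl_us", "c_vhr", "c_vscl",
    "period_v_s", "period_hr_s",
    grep("^(a1_)?(fz|cz)_(sta|dev)_(n1|p2)_(amp_uv|lat_ms)$",
         names(s), value = TRUE)
  )
  vars <- vars[vars %in% names(s)]
  purrr::map_dfr(vars, function(v) {
    x1 <- s[[v]][g1]
    x2 <- s[[v]][g2]
    x1 <- x1[!is.na(x1)]
    x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2 ||
        (pop_sd(x1) == 0 && pop_sd(x2) == 0)) {
      return(tibble(measure = v, method = NA_character_))
    }
    res <- compare_groups(x1, x2)
    res <- dplyr::bind_cols(
      tibble(measure = v,
             mean_I = mean(x1), sd_I = sd(x1),
             mean_II = mean(x2), sd_II = sd(x2)),
      res
    )
    res
  })
}

#' @export
print.cohort_result <- function(x, ...) {
  n <- nrow(x$summaries)
  cat(sprintf(
    "Cohort of %d subjects: %d in Group I (with delay), %d in Group II\n",
    n, sum(x$summaries$group == "I"), sum(x$summaries$group == "II")
  ))
  invisible(x)
}
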