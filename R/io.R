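#' Read a 1-Hz series file
#'
#' Series files are UTF-8 tab-separated with a header row and columns
#' `time_s` (integer seconds, strictly increasing by 1), `value`
#' (float) and `mask` (0/1). Violations raise errors naming the
#' offending line (header = line 1).
#'
#' @param path File path.
#' @param label Signal label to attach; defaults to the file name stem.
#' @return A `uniform_series`.
#' @export
read_series <- function(path, label = NULL) {
  df <- readr::read_tsv(path, col_types = "ddd", progress = FALSE)
  need <- c("time_s", "value", "mask")
  if (!identical(names(df), need)) {
    abort(sprintf(
      "%s: header must be 'time_s\\tvalue\\tmask' (line 1), got: %s",
      path, paste(names(df), collapse = ", ")
    ))
  }
  bad_na <- which(!complete.cases(df))
  if (length(bad_na) > 0) {
    abort(sprintf("%s: missing cell at line %d.", path, bad_na[1] + 1L))
  }
  steps <- diff(df$time_s)
  bad <- which(steps != 1)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: time_s must increase by 1 s; violation at line %d (t=%g -> t=%g).",
      path, bad[1] + 2L, df$time_s[bad[1]], df$time_s[bad[1] + 1]
    ))
  }
  if (!all(df$mask %in% c(0, 1))) {
    abort(sprintf("%s: mask must be 0/1.", path))
  }
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  out <- uniform_series(df$value, mask = df$mask == 1, label = label,
                        t0 = df$time_s[1])
  out
}

#' @rdname read_series
#' @param series A `uniform_series` to write.
#' @export
write_series <- function(series, path) {
  validate_uniform_series(series)
  df <- tibble(
    time_s = as.integer(series$time_s),
    # masked samples may hold NA in memory; the file contract requires a
    # numeric cell, and masked values are never used downstream
    value = ifelse(is.na(series$value), 0, series$value),
    mask = as.integer(series$mask)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write an epoch stream file
#'
#' Epoch files are tab-separated with one row per epoch: columns
#' `subject_id`, `stimulus_idx`, `onset_s`, `stimulus_type`, `stage`,
#' `channel`, `follows_deviant`, then 900 sample columns `s0..s899`
#' (microvolts, -100..+799 ms at 1 kHz).
#'
#' @param path File path.
#' @return A tibble in the in-memory epoch layout (see [erp_epochs])
#'   with an additional `subject_id` column.
#' @export
read_epochs <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  sample_cols <- paste0("s", 0:(EPOCH_LEN - 1))
  miss <- setdiff(sample_cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing %d sample column(s), e.g. %s.",
                  path, length(miss), miss[1]))
  }
  if (is.unsorted(df$stimulus_idx, strictly = TRUE)) {
    abort(sprintf("%s: stimulus_idx must be strictly increasing.", path))
  }
  m <- as.matrix(df[, sample_cols])
  tibble(
    subject_id = df$subject_id,
    epoch_idx = df$stimulus_idx,
    onset_s = df$onset_s,
    stimulus_type = df$stimulus_type,
    stage = as.integer(df$stage),
    channel = df$channel,
    follows_deviant = as.logical(df$follows_deviant),
    samples = purrr::map(seq_len(nrow(m)), function(i) unname(m[i, ]))
  )
}

#' @rdname read_epochs
#' @param epochs Epoch tibble.
#' @param subject_id Identifier written into the file.
#' @export
write_epochs <- function(epochs, path, subject_id = "S01") {
  m <- do.call(rbind, epochs$samples)
  colnames(m) <- paste0("s", 0:(ncol(m) - 1))
  df <- dplyr::bind_cols(
    tibble(
      subject_id = subject_id,
      stimulus_idx = epochs$epoch_idx,
      onset_s = epochs$onset_s,
      stimulus_type = epochs$stimulus_type,
      stage = epochs$stage,
      channel = epochs$channel,
      follows_deviant = as.integer(epochs$follows_deviant)
    ),
    as_tibble(m)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Write / read a subject record directory
#'
#' One directory per subject: `v.tsv`, `hr.tsv`, `scl.tsv` series
#' files, optional `epochs.tsv`, and `meta.json` (subject id,
#' falling-asleep count, generator parameters when synthetic).
#'
#' @param record A `subject_record`.
#' @param dir Directory (created if needed).
#' @return `write_subject_record()` the directory, invisibly;
#'   `read_subject_record()` a `subject_record`.
#' @export
write_subject_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_series(record$v, file.path(dir, "v.tsv"))
  write_series(record$hr, file.path(dir, "hr.tsv"))
  write_series(record$scl, file.path(dir, "scl.tsv"))
  if (!is.null(record$epochs)) {
    write_epochs(record$epochs, file.path(dir, "epochs.tsv"),
                 subject_id = record$subject_id)
  }
  meta <- list(
    subject_id = record$subject_id,
    falling_asleep_count = record$falling_asleep_count,
    params = if (is.null(record$params)) NULL else unclass(record$params)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_subject_record
#' @export
read_subject_record <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  epochs_path <- file.path(dir, "epochs.tsv")
  structure(
    list(
      subject_id = meta$subject_id,
      v = read_series(file.path(dir, "v.tsv"), label = "V"),
      hr = read_series(file.path(dir, "hr.tsv"), label = "HR"),
      scl = read_series(file.path(dir, "scl.tsv"), label = "SCL"),
      epochs = if (file.exists(epochs_path)) read_epochs(epochs_path) else NULL,
      falling_asleep_count = meta$falling_asleep_count,
      params = meta$params
    ),
    class = "subject_record"
  )
}

#' Write cohort result tables with a run manifest
#'
#' Each tibble in `tables` is written as `<name>.tsv` (floats at 6
#' significant digits); `manifest.json` records the configuration,
#' seed, package version and timestamp, enough to re-run the analysis.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @param config Configuration list stored in the manifest.
#' @param seed Seed stored in the manifest.
#' @return Invisible character vector of files written.
#' @export
write_results <- function(tables, dir, config = NULL, seed = NULL) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("`tables` must be a fully named list.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::imap_chr(tables, function(tab, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    tab <- as_tibble(tab)
    tab[] <- lapply(tab, function(col) {
      if (is.numeric(col)) signif(col, 6) else col
    })
    readr::write_tsv(tab, p, progress = FALSE)
    p
  })
  manifest <- list(
    package = "vigicouple",
    version = as.character(utils::packageVersion("vigicouple")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = config,
    tables = names(tables)
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(c(paths, mp))
}

#' Read an analysis configuration from YAML
#'
#' The YAML file may set any argument of [analysis_config()] (unknown
#' keys raise an error) plus optional `synth:` and `erp:` blocks
#' forwarded to [synth_params()] / [erp_synth_params()].
#'
#' @param path YAML file path.
#' @return List with elements `config`, `synth` (or `NULL`), `erp` (or
#'   `NULL`).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg_keys <- setdiff(names(y), c("synth", "erp"))
  unknown <- setdiff(cfg_keys, names(formals(analysis_config)))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  config <- do.call(analysis_config, y[cfg_keys])
  synth <- if (!is.null(y$synth)) do.call(synth_params, y$synth) else NULL
  erp <- if (!is.null(y$erp)) do.call(erp_synth_params, y$erp) else NULL
  list(config = config, synth = synth, erp = erp)
}
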