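#' Read a spectrum frame file
#'
#' Spectrum frames are plain CSV with two numeric columns,
#' `wavelength_nm` and `intensity`, preceded by optional `#`-prefixed
#' header lines carrying metadata (`# channel: ch1`,
#' `# timestamp_s: 12`). Wavelengths must be strictly increasing and
#' intensities finite and non-negative; violations raise a format error
#' naming the offending row.
#'
#' @param path Path to a spectrum CSV file.
#' @return A tibble of class `fp_spectrum`.
#' @export
read_spectrum_file <- function(path) {
  if (!file.exists(path)) {
    fp_abort(sprintf("File not found: %s", path), "fp_format_error")
  }
  meta <- read_hash_header(path)
  # base read.csv parses doubles via strtod (correctly rounded), so the
  # %.17g writer round-trips bit-exactly
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#"),
    error = function(e) {
      fp_abort(sprintf("Cannot parse %s as CSV: %s", path,
                       conditionMessage(e)), "fp_format_error")
    })
  if (!all(c("wavelength_nm", "intensity") %in% names(df))) {
    fp_abort(sprintf(
      "%s: missing column(s) %s.", path,
      paste(setdiff(c("wavelength_nm", "intensity"), names(df)),
            collapse = ", ")), "fp_format_error")
  }
  ts <- suppressWarnings(as.numeric(meta[["timestamp_s"]] %||% NA))
  as_fp_spectrum(df, timestamp_s = ts,
                 channel = meta[["channel"]] %||% NA_character_)
}

read_hash_header <- function(path) {
  meta <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "#")) break
    kv <- sub("^#\\s*", "", line)
    m <- regmatches(kv, regexec("^([^:]+):\\s*(.*)$", kv))[[1]]
    if (length(m) == 3) meta[trimws(m[2])] <- trimws(m[3])
  }
  as.list(meta)
}

#' Write a spectrum frame file
#'
#' Inverse of [read_spectrum_file()]; the round trip is lossless at full
#' double precision.
#'
#' @param spectrum An `fp_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_file <- function(spectrum, path) {
  if (!inherits(spectrum, "fp_spectrum")) {
    spectrum <- as_fp_spectrum(spectrum)
  }
  header <- c(
    sprintf("# channel: %s", attr(spectrum, "channel") %||% NA),
    sprintf("# timestamp_s: %s",
            format(attr(spectrum, "timestamp_s") %||% NA, digits = 17))
  )
  # %.17g guarantees bit-exact round trip of doubles through text
  body <- sprintf("%.17g,%.17g", spectrum$wavelength_nm,
                  spectrum$intensity)
  writeLines(c(header, "wavelength_nm,intensity", body), path)
  invisible(path)
}

#' Read or write an interrogator-style peak table
#'
#' Peak tables are CSV files with columns `timestamp_s`, `channel`,
#' `peak_index`, `wavelength_nm`, `intensity` — the export format of a
#' multi-channel interrogator's peak tracker. [demodulate_peaks()]
#' accepts one (timestamp, channel) group at a time.
#'
#' @param path File path.
#' @param peaks For writing: a peaks tibble (from [detect_peaks()] or
#'   assembled manually).
#' @return `read_peak_table()` returns a tibble; `write_peak_table()`
#'   returns `path` invisibly.
#' @export
read_peak_table <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("timestamp_s", "channel", "peak_index", "wavelength_nm",
            "intensity")
  if (!all(need %in% names(df))) {
    fp_abort(sprintf("%s: missing column(s) %s.", path,
                     paste(setdiff(need, names(df)), collapse = ", ")),
             "fp_format_error")
  }
  df
}

#' @rdname read_peak_table
#' @export
write_peak_table <- function(peaks, path) {
  out <- tibble::as_tibble(peaks)
  if (!"timestamp_s" %in% names(out)) {
    out$timestamp_s <- attr(peaks, "timestamp_s") %||% NA_real_
  }
  if (!"channel" %in% names(out)) {
    out$channel <- attr(peaks, "channel") %||% NA_character_
  }
  out <- dplyr::select(out, "timestamp_s", "channel", "peak_index",
                       "wavelength_nm", "intensity")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read or write a cavity-length time-series file
#'
#' Time series are CSV files with columns `timestamp_s`, `channel`,
#' `d_um`, `k`, `flag` (units in the column names).
#'
#' @param path File path.
#' @param series For writing: an `fp_series` tibble from [track()].
#' @return `read_timeseries()` returns an `fp_series` tibble;
#'   `write_timeseries()` returns `path` invisibly.
#' @export
read_timeseries <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("timestamp_s", "channel", "d_um", "k", "flag")
  if (!all(need %in% names(df))) {
    fp_abort(sprintf("%s: missing column(s) %s.", path,
                     paste(setdiff(need, names(df)), collapse = ", ")),
             "fp_format_error")
  }
  out <- tibble::as_tibble(df)
  class(out) <- c("fp_series", class(out))
  out
}

#' @rdname read_timeseries
#' @export
write_timeseries <- function(series, path) {
  need <- c("timestamp_s", "channel", "d_um", "k", "flag")
  if (!all(need %in% names(series))) {
    fp_abort("`series` lacks the time-series columns.", "fp_invalid_input")
  }
  readr::write_csv(tibble::as_tibble(series)[need], path, progress = FALSE)
  invisible(path)
}

#' Write an expansion summary report
#'
#' Writes the summary as a JSON document (per-activation table, error
#' statistics, baseline SDs and a config echo of geometry, roles and
#' schedule) plus a companion CSV of the per-activation table.
#'
#' @param summary An `expansion_summary` from [summarize_expansion()].
#' @param json_path Output JSON path.
#' @param csv_path Output CSV path; default replaces the JSON extension.
#' @return `json_path`, invisibly.
#' @export
write_expansion_report <- function(summary, json_path,
                                   csv_path = sub("\\.json$", ".csv",
                                                  json_path)) {
  stopifnot(inherits(summary, "expansion_summary"))
  doc <- list(
    activations = summary$activations,
    error_mean_um = summary$error_mean_um,
    error_sd_um = summary$error_sd_um,
    baseline_sd_um = as.list(summary$baseline_sd_um),
    config = list(
      geometry = unclass(summary$geometry),
      roles = as.list(summary$roles),
      schedule_turns = summary$schedule
    )
  )
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  readr::write_csv(summary$activations, csv_path, progress = FALSE)
  invisible(json_path)
}

#' Write or read a synthetic dataset directory
#'
#' A dataset directory holds one sub-directory per channel with a
#' spectrum CSV per frame, a `ground_truth.csv` and a `config.yaml`
#' echoing the generating configuration — everything needed to re-run
#' the demodulation pipeline from files alone.
#'
#' @param experiment An `fp_experiment`.
#' @param dir Dataset directory (created if needed).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a list with `frames` (named list per channel) and, when
#'   present, `ground_truth`.
#' @export
write_dataset <- function(experiment, dir) {
  stopifnot(inherits(experiment, "fp_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(experiment$frames)) {
    chdir <- file.path(dir, ch)
    dir.create(chdir, showWarnings = FALSE)
    frames <- experiment$frames[[ch]]
    for (i in seq_along(frames)) {
      write_spectrum_file(frames[[i]],
                          file.path(chdir, sprintf("frame_%06d.csv", i)))
    }
  }
  readr::write_csv(experiment$ground_truth,
                   file.path(dir, "ground_truth.csv"), progress = FALSE)
  cfg <- experiment$config
  if (inherits(cfg, "fp_experiment_config")) {
    cfg <- unclass(cfg)
    cfg$geometry <- unclass(cfg$geometry)
    cfg$cavity_template <- unclass(cfg$cavity_template)
    cfg$step_um <- lapply(cfg$step_um, as.numeric)
    cfg$initial_d_um <- as.list(cfg$initial_d_um)
    cfg$roles <- as.list(cfg$roles)
  }
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  if (!dir.exists(dir)) {
    fp_abort(sprintf("Dataset directory not found: %s", dir),
             "fp_format_error")
  }
  chdirs <- list.dirs(dir, recursive = FALSE)
  frames <- list()
  for (chdir in chdirs) {
    files <- sort(list.files(chdir, pattern = "\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0) next
    frames[[basename(chdir)]] <- lapply(files, read_spectrum_file)
  }
  if (length(frames) == 0) {
    fp_abort(sprintf("No frame files found under %s.", dir),
             "fp_format_error")
  }
  gt_path <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path)) {
    readr::read_csv(gt_path, show_col_types = FALSE, progress = FALSE)
  } else {
    NULL
  }
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  list(frames = frames, ground_truth = gt, config = cfg)
}
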