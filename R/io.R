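# Plain-text interchange: one CSV per recording (time_s, value_uV) plus a
# JSON manifest (sampling rate, condition timeline, subject metadata, and
# the ground-truth gain envelope when known), and tidy CSVs for the
# behavioral tables.

#' Write a recording to CSV + JSON manifest
#'
#' @param recording A `bw_recording`.
#' @param csv_path Path of the sample CSV (columns `time_s`, `value_uV`).
#' @param manifest_path Path of the JSON manifest (default: `csv_path`
#'   with a `.json` extension).
#' @return Invisibly, the manifest path.
#' @export
write_recording <- function(recording, csv_path,
                            manifest_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(recording, "bw_recording"))
  n <- length(recording$samples)
  # %.17g guarantees the doubles round-trip bit-identically through text
  dt <- data.table::data.table(
    time_s = sprintf("%.17g", (seq_len(n) - 1L) / recording$sampling_rate),
    value_uV = sprintf("%.17g", recording$samples))
  data.table::fwrite(dt, csv_path, quote = FALSE)
  manifest <- list(
    sampling_rate = recording$sampling_rate,
    n_samples = n,
    timeline = as.data.frame(recording$timeline),
    subject_meta = recording$subject_meta,
    ground_truth = if (!is.null(recording$ground_truth)) {
      gt <- as.data.frame(recording$ground_truth)
      # JSON has no Inf; write halftimes as strings and re-parse on load
      gt$halftime_min <- as.character(gt$halftime_min)
      gt
    })
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest_path)
}

#' Load a recording from CSV + JSON manifest
#'
#' Validates that the time column is uniformly sampled, infers the
#' sampling rate from it, and cross-checks it against the manifest (a
#' mismatch above 0.1% is an error). The condition timeline is
#' re-validated on load.
#'
#' @param csv_path Path of the sample CSV (columns `time_s`, `value_uV`).
#' @param manifest_path Path of the JSON manifest.
#' @return A `bw_recording`.
#' @export
load_recording <- function(csv_path,
                           manifest_path = sub("\\.csv$", ".json", csv_path)) {
  dt <- data.table::fread(csv_path)
  if (!all(c("time_s", "value_uV") %in% names(dt)))
    stop("load error: CSV must have columns time_s and value_uV")
  if (nrow(dt) < 2L) stop("load error: recording too short")
  dts <- diff(dt$time_s)
  dt_med <- stats::median(dts)
  if (dt_med <= 0 || any(abs(dts - dt_med) > 1e-6 * dt_med + 1e-12))
    stop("load error: non-uniform sampling in time_s column")
  rate_csv <- 1 / dt_med

  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(manifest$sampling_rate))
    stop("load error: manifest lacks sampling_rate")
  if (abs(rate_csv - manifest$sampling_rate) > 1e-3 * manifest$sampling_rate)
    stop("load error: sampling rate from CSV (", signif(rate_csv, 8),
         " Hz) disagrees with manifest (", manifest$sampling_rate,
         " Hz) by more than 0.1%")
  timeline <- as_bw_timeline(as.data.frame(manifest$timeline))
  gt <- NULL
  if (!is.null(manifest$ground_truth) && length(manifest$ground_truth)) {
    gt <- as.data.frame(manifest$ground_truth)
    # jsonlite serializes Inf halftimes as the string "Inf"
    for (cl in setdiff(names(gt), "condition")) gt[[cl]] <- as.numeric(gt[[cl]])
    class(gt) <- c("bw_envelope", "data.frame")
  }
  if (any(is.na(dt$value_uV)))
    stop("load error: recording contains missing samples")
  structure(
    list(samples = dt$value_uV, sampling_rate = manifest$sampling_rate,
         timeline = timeline,
         subject_meta = manifest$subject_meta %||% list(),
         ground_truth = gt),
    class = "bw_recording")
}

#' Write the behavioral study tables as tidy CSVs
#'
#' Writes `latency.csv`, `intake.csv`, and `weight.csv` into a directory.
#'
#' @param study A `bw_behavior_study` (or list with those tables).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_behavior_tables <- function(study, dir) {
  check_behavior_dataset(study)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(study$latency, file.path(dir, "latency.csv"))
  data.table::fwrite(study$intake, file.path(dir, "intake.csv"))
  data.table::fwrite(study$weight, file.path(dir, "weight.csv"))
  invisible(dir)
}

#' Read behavioral study tables from a directory of tidy CSVs
#'
#' @param dir Directory containing `latency.csv`, `intake.csv`,
#'   `weight.csv`.
#' @return A list of data.frames (`latency`, `intake`, `weight`).
#' @export
read_behavior_tables <- function(dir) {
  paths <- file.path(dir, c("latency.csv", "intake.csv", "weight.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("behavior error: missing table file(s): ",
         paste(basename(missing), collapse = ", "))
  out <- lapply(paths, function(p) as.data.frame(data.table::fread(p)))
  names(out) <- c("latency", "intake", "weight")
  check_behavior_dataset(out)
  out
}

#' Export a spectrum as CSV
#'
#' @param spectrum A `bw_spectrum`.
#' @param path Output CSV path (columns `freq_hz`, `power_uv2_per_hz`).
#' @return Invisibly, the path.
#' @export
write_spectrum <- function(spectrum, path) {
  data.table::fwrite(data.table::data.table(freq_hz = spectrum$freqs,
                                            power_uv2_per_hz = spectrum$power),
                     path)
  invisible(path)
}
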