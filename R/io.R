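# CSV interchange: waveform files (time_s, ch1, ch2, ch3), reference
# tables, and the feature table.

.feature_csv_cols <- c("record_id", "subject_id", "heart_rate_bpm",
                       "systolic_peak_amp", "dicrotic_peak_amp", "dp1_amp",
                       "dp2_amp", "notch_amp", "max_slope", "aug_index",
                       "t1_s", "t2_s", "t3_s", "sbp_mmHg", "dbp_mmHg")

#' Write a multi-channel waveform recording to CSV
#'
#' Header `time_s,ch1,ch2,...`, one row per sample.
#'
#' @param recording a `pulse_recording` (or samples x channels matrix with a
#'   `sampling_rate_hz` argument).
#' @param path output file.
#' @param sampling_rate_hz required for matrix input.
#' @export
write_waveform_csv <- function(recording, path, sampling_rate_hz = NULL) {
  if (inherits(recording, "pulse_recording")) {
    ch <- recording$channels
    fs <- recording$sampling_rate_hz
  } else {
    ch <- as.matrix(recording)
    fs <- sampling_rate_hz
    if (is.null(fs)) stop("sampling_rate_hz required for a matrix input")
  }
  df <- data.frame(time_s = (seq_len(nrow(ch)) - 1) / fs, ch)
  colnames(df) <- c("time_s", paste0("ch", seq_len(ncol(ch))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a waveform CSV written by [write_waveform_csv()]
#'
#' @param path file path.
#' @return list with `channels` matrix, `sampling_rate_hz` (inferred from
#'   the time column) and `time_s`.
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  if (colnames(df)[1] != "time_s") stop("expected a time_s column first")
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing")
  list(channels = as.matrix(df[, -1, drop = FALSE]),
       sampling_rate_hz = 1 / stats::median(dt),
       time_s = df$time_s)
}

#' Write a reference-pressure table to CSV
#'
#' Header `record_id,subject_id,sbp_mmHg,dbp_mmHg`.
#'
#' @param references data.frame with those four columns.
#' @param path output file.
#' @export
write_reference_csv <- function(references, path) {
  utils::write.csv(references[, c("record_id", "subject_id", "sbp_mmHg",
                                  "dbp_mmHg")], path, row.names = FALSE)
  invisible(path)
}

#' Write the labelled feature table to CSV
#'
#' One row per accepted record with the eleven waveform features and the
#' reference pressures.
#'
#' @param features data.frame containing the feature-table columns.
#' @param path output file.
#' @export
write_feature_csv <- function(features, path) {
  missing_cols <- setdiff(.feature_csv_cols, colnames(features))
  if (length(missing_cols))
    stop("feature table missing column(s): ", paste(missing_cols, collapse = ", "))
  utils::write.csv(features[, .feature_csv_cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#'
#' @param path file path.
#' @return data.frame in the [write_feature_csv()] column layout.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.feature_csv_cols, colnames(df))
  if (length(missing_cols))
    stop("feature table missing column(s): ", paste(missing_cols, collapse = ", "))
  df
}

#' Write a ground-truth ledger as JSON
#'
#' Structured text dump of per-record ground truth (reference pressures,
#' aligned channel, per-beat fiducial times) for test oracles.
#'
#' @param dataset a [generate_dataset()] result.
#' @param path output file.
#' @export
write_ground_truth_json <- function(dataset, path) {
  gt <- lapply(dataset$records, function(r)
    list(record_id = r$record_id, subject_id = r$subject_id,
         sbp_mmHg = r$ground_truth$sbp_mmHg,
         dbp_mmHg = r$ground_truth$dbp_mmHg,
         aligned_channel = r$ground_truth$aligned_channel,
         fiducials = r$ground_truth$fiducials))
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
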