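# Recording and table round-tripping. CSV is the canonical interchange
# format: one header row, a time column in ms, and one column per channel.

#' Write a recording to CSV
#'
#' Columns: `time_ms`, `ecg` (mV), `lap` (mmHg), `cs` (mV).
#'
#' @param recording a `pacing_recording`.
#' @param path output file.
#' @export
write_recording_csv <- function(recording, path) {
  n <- length(recording$channels$ecg)
  df <- data.frame(time_ms = (seq_len(n) - 1) * 1000 / recording$sample_rate,
                   ecg = recording$channels$ecg,
                   lap = recording$channels$lap,
                   cs = recording$channels$cs)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Expects a header with a time column (ms) and the three channels; the
#' channel map argument accommodates recordings whose columns are named
#' differently.
#'
#' @param path CSV file.
#' @param channel_map named list mapping `ecg`, `lap`, `cs` (and optional
#'   `time`) to column names in the file.
#' @param patient_id identifier attached to the recording.
#' @return a `pacing_recording`.
#' @export
read_recording_csv <- function(path,
                               channel_map = list(time = "time_ms",
                                                  ecg = "ecg", lap = "lap",
                                                  cs = "cs"),
                               patient_id = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  for (ch in c("ecg", "lap", "cs"))
    if (!channel_map[[ch]] %in% names(df))
      stop(sprintf("channel column '%s' not found in %s",
                   channel_map[[ch]], path), call. = FALSE)
  tcol <- channel_map$time
  if (!is.null(tcol) && tcol %in% names(df) && nrow(df) > 1) {
    dt_ms <- stats::median(diff(df[[tcol]]))
    fs <- round(1000 / dt_ms)
  } else {
    fs <- 1000
  }
  structure(list(sample_rate = fs,
                 channels = list(ecg = df[[channel_map$ecg]],
                                 lap = df[[channel_map$lap]],
                                 cs = df[[channel_map$cs]]),
                 patient_id = patient_id),
            class = "pacing_recording")
}
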