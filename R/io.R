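#' Read and write the package's CSV dialects
#'
#' Gaze CSV: columns `time_ms, xL_deg, yL_deg, pupilL, xR_deg, yR_deg,
#' pupilR`, missing data as empty fields. Schedule CSV: `trial_id,
#' block_type, foreperiod_ms, cue_onset_ms, target_onset_ms, iti_ms`.
#' Events CSV: `kind, onset_ms, offset_ms, amplitude_deg,
#' peak_velocity_dps` (ground truth) or the detector's per-trial events.
#'
#' @param recording,file A `gaze_recording` and a file path.
#' @return `read_gaze_csv` returns a `gaze_recording`; writers return the
#'   file path invisibly.
#' @name gaze_io
NULL

#' @rdname gaze_io
#' @export
write_gaze_csv <- function(recording, file) {
  utils::write.csv(as.data.frame(recording), file, row.names = FALSE,
                   na = "")
  invisible(file)
}

#' @rdname gaze_io
#' @export
read_gaze_csv <- function(file) {
  df <- utils::read.csv(file, na.strings = "")
  need <- c("time_ms", "xL_deg", "yL_deg", "pupilL", "xR_deg", "yR_deg",
            "pupilR")
  if (!all(need %in% names(df))) {
    stop("gaze CSV must have columns: ", paste(need, collapse = ", "))
  }
  attr(df, "sampling_rate") <- 1000
  class(df) <- c("gaze_recording", "data.frame")
  df
}

#' @rdname gaze_io
#' @param schedule A `trial_schedule`.
#' @export
write_schedule_csv <- function(schedule, file) {
  utils::write.csv(as.data.frame(schedule), file, row.names = FALSE)
  invisible(file)
}

#' @rdname gaze_io
#' @export
read_schedule_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  class(df) <- c("trial_schedule", "data.frame")
  df
}

#' @rdname gaze_io
#' @param truth A ground-truth list from [simulate_gaze()].
#' @export
write_truth_csv <- function(truth, file) {
  ev <- rbind(
    data.frame(kind = "saccade", onset_ms = truth$saccade_onset_ms,
               offset_ms = truth$saccade_onset_ms + truth$saccade_duration_ms,
               amplitude_deg = truth$saccade_amplitude_deg,
               peak_velocity_dps = truth$saccade_peak_velocity_dps),
    data.frame(kind = "blink", onset_ms = truth$blink_onset_ms,
               offset_ms = truth$blink_offset_ms,
               amplitude_deg = NA_real_, peak_velocity_dps = NA_real_))
  utils::write.csv(ev, file, row.names = FALSE, na = "")
  invisible(file)
}

#' Minimal EyeLink ASC sample import
#'
#' Parses binocular sample lines of an EyeLink ASC export: whitespace-
#' separated `timestamp xL yL pupilL xR yR pupilR [...]` with missing data
#' as dots. Message, event and header lines (anything whose first field is
#' not a number) are skipped; full ASC message parsing is out of scope.
#' Positions are returned as-is (the caller converts pixels to degrees if
#' needed).
#'
#' @param file Path to an ASC file.
#' @return A `gaze_recording`.
#' @export
read_asc_samples <- function(file) {
  lines <- readLines(file, warn = FALSE)
  keep <- grepl("^\\s*\\d", lines)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  fields <- fields[vapply(fields, length, integer(1)) >= 7]
  if (length(fields) == 0) stop("no sample lines found in ", file)
  num <- function(i) {
    v <- vapply(fields, `[`, character(1), i)
    suppressWarnings(as.numeric(v))     # "." (missing) becomes NA
  }
  df <- data.frame(time_ms = num(1), xL_deg = num(2), yL_deg = num(3),
                   pupilL = num(4), xR_deg = num(5), yR_deg = num(6),
                   pupilR = num(7))
  attr(df, "sampling_rate") <- 1000
  class(df) <- c("gaze_recording", "data.frame")
  df
}
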