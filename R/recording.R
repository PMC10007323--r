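# Recording and envelope-epoch containers plus their delimited-text I/O.

#' Construct a multichannel EMG recording
#'
#' A recording holds the continuous channels x samples signal matrix for one
#' participant together with trial markers. Marker onsets are 0-based sample
#' indices into the signal; every marker must leave room for the full epoch
#' window of 500 ms pre-stimulus baseline and 5000 ms action period
#' (half-open, `[onset - 0.5 s, onset + 5 s)`).
#'
#' @param participant_id Single string identifying the participant.
#' @param signal Numeric matrix, channels x samples. Row names, if present,
#'   must match `channel_names`.
#' @param markers Data frame with columns `onset_sample` (0-based integers,
#'   sorted ascending) and `condition` (values from [condition_labels()]).
#' @param sampling_rate Sampling rate in Hz (default 1000).
#' @param channel_names Character vector naming the rows of `signal`
#'   (default [muscle_names()]).
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(participant_id, signal, markers,
                          sampling_rate = 1000,
                          channel_names = muscle_names()) {
  rec <- structure(
    list(participant_id = as.character(participant_id),
         sampling_rate = sampling_rate,
         channel_names = as.character(channel_names),
         signal = signal,
         markers = as.data.frame(markers)),
    class = "emg_recording")
  validate_recording(rec)
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  if (!is.numeric(rec$sampling_rate) || length(rec$sampling_rate) != 1 ||
      rec$sampling_rate <= 0) {
    stop("invalid recording: sampling_rate must be a single positive number",
         call. = FALSE)
  }
  if (!is.matrix(rec$signal) || !is.numeric(rec$signal)) {
    stop("invalid recording: signal must be a numeric matrix", call. = FALSE)
  }
  if (nrow(rec$signal) != length(rec$channel_names)) {
    stop("invalid recording: signal has ", nrow(rec$signal),
         " rows but there are ", length(rec$channel_names),
         " channel names", call. = FALSE)
  }
  mk <- rec$markers
  if (!all(c("onset_sample", "condition") %in% names(mk))) {
    stop("invalid recording: markers need onset_sample and condition columns",
         call. = FALSE)
  }
  assert_condition(as.character(mk$condition))
  if (nrow(mk) > 1 && is.unsorted(mk$onset_sample)) {
    stop("invalid recording: markers must be sorted by onset_sample",
         call. = FALSE)
  }
  pre <- round(0.5 * rec$sampling_rate)
  post <- round(5 * rec$sampling_rate)
  ok <- mk$onset_sample - pre >= 0 &
    mk$onset_sample + post <= ncol(rec$signal)
  if (!all(ok)) {
    stop("invalid recording: marker(s) ", paste(which(!ok), collapse = ", "),
         " do not allow a full [-500 ms, +5000 ms) epoch window",
         call. = FALSE)
  }
  rec
}

#' @export
print.emg_recording <- function(x, ...) {
  cat("<emg_recording> participant", x$participant_id, "\n")
  cat(" ", nrow(x$signal), "channels x", ncol(x$signal), "samples @",
      x$sampling_rate, "Hz;", nrow(x$markers), "trial markers\n")
  invisible(x)
}

#' Write a recording to a CSV/JSON file pair
#'
#' Emits `<path>.csv` (samples x channels, header = channel names) and a
#' `<path>.json` sidecar carrying participant id, sampling rate, channel
#' order and trial markers. The pair round-trips through
#' [read_recording()] losslessly up to numeric text precision.
#'
#' @param rec A validated [emg_recording()].
#' @param path Output path; a trailing `.csv` is stripped.
#' @return `path` (base, without extension), invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  base <- sub("\\.csv$", "", path)
  df <- as.data.frame(t(rec$signal))
  names(df) <- rec$channel_names
  write.csv(df, paste0(base, ".csv"), row.names = FALSE)
  meta <- list(participant_id = rec$participant_id,
               sampling_rate = rec$sampling_rate,
               channel_names = rec$channel_names,
               markers = rec$markers)
  jsonlite::write_json(meta, paste0(base, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Path to the `.csv` file or the extensionless base path; the
#'   `.json` sidecar must sit alongside.
#' @return A validated [emg_recording()]. Channel order is taken from the
#'   sidecar.
#' @export
read_recording <- function(path) {
  base <- sub("\\.csv$", "", path)
  csv <- paste0(base, ".csv")
  sidecar <- paste0(base, ".json")
  if (!file.exists(sidecar)) {
    stop("missing sidecar file: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- read.csv(csv, check.names = FALSE)
  if (ncol(df) != length(meta$channel_names)) {
    stop("channel count mismatch: sidecar lists ",
         length(meta$channel_names), " channels, file has ", ncol(df),
         " columns", call. = FALSE)
  }
  sig <- t(as.matrix(df[meta$channel_names]))
  dimnames(sig) <- NULL
  markers <- as.data.frame(meta$markers)
  markers$onset_sample <- as.integer(markers$onset_sample)
  emg_recording(meta$participant_id, sig, markers,
                sampling_rate = meta$sampling_rate,
                channel_names = meta$channel_names)
}

#' Construct envelope epochs
#'
#' Holds the trials x channels x timepoints array of 10 Hz ARV envelopes for
#' one participant, partitioned into `n_baseline` pre-stimulus points and
#' `n_stimulus` action-period points.
#'
#' @param participant_id Single string.
#' @param data Numeric array, trials x channels x timepoints.
#' @param conditions Per-trial condition labels (length = number of trials).
#' @param envelope_rate Envelope sampling rate in Hz (default 10).
#' @param n_baseline Number of pre-stimulus points (default 5).
#' @param n_stimulus Number of action-period points (default 50).
#' @param channel_names Channel labels (default [muscle_names()]).
#' @param version `"original"` (rectified envelopes, checked nonnegative) or
#'   `"reconstructed"` (back-projections, may go negative).
#' @return An object of class `emg_epochs`.
#' @export
emg_epochs <- function(participant_id, data, conditions,
                       envelope_rate = 10, n_baseline = 5, n_stimulus = 50,
                       channel_names = muscle_names(),
                       version = c("original", "reconstructed")) {
  version <- match.arg(version)
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("data must be a trials x channels x timepoints array", call. = FALSE)
  }
  if (dim(data)[3] != n_baseline + n_stimulus) {
    stop("timepoints (", dim(data)[3], ") != n_baseline + n_stimulus (",
         n_baseline + n_stimulus, ")", call. = FALSE)
  }
  if (dim(data)[1] != length(conditions)) {
    stop("number of trials (", dim(data)[1], ") != length of conditions (",
         length(conditions), ")", call. = FALSE)
  }
  if (dim(data)[2] != length(channel_names)) {
    stop("number of channels != length of channel_names", call. = FALSE)
  }
  assert_condition(as.character(conditions))
  if (version == "original" && any(data < 0)) {
    stop("original envelopes must be nonnegative", call. = FALSE)
  }
  structure(
    list(participant_id = as.character(participant_id),
         envelope_rate = envelope_rate,
         data = data,
         n_baseline = n_baseline,
         n_stimulus = n_stimulus,
         conditions = as.character(conditions),
         channel_names = as.character(channel_names),
         version = version),
    class = "emg_epochs")
}

#' @export
print.emg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<emg_epochs> participant", x$participant_id, paste0("(", x$version, ")\n"))
  cat(" ", d[1], "trials x", d[2], "channels x", d[3], "points @",
      x$envelope_rate, "Hz (", x$n_baseline, "baseline +", x$n_stimulus,
      "stimulus )\n")
  invisible(x)
}

#' Write a statistics or condition-summary table as CSV
#'
#' @param rows A nonempty data frame (e.g. from [build_report()] or
#'   [summarize_conditions()]), or a list of data frames with identical
#'   columns which are then row-bound.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(rows, path) {
  if (is.list(rows) && !is.data.frame(rows)) {
    if (length(rows) == 0) stop("rows must be nonempty", call. = FALSE)
    cols <- lapply(rows, names)
    if (!all(vapply(cols, identical, logical(1), cols[[1]]))) {
      stop("rows are not homogeneous: mixed column sets", call. = FALSE)
    }
    rows <- do.call(rbind, rows)
  }
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    stop("rows must be a nonempty data frame", call. = FALSE)
  }
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
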