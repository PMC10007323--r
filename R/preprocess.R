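# Raw signal -> 10 Hz rectified (ARV) envelope epochs.
#
# The order of operations is fixed: bandpass -> rectify -> bin-mean
# downsample -> epoch -> concatenate. Rectification must precede
# downsampling: averaging a zero-mean signal first would cancel it.

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass, applied per
#' channel. Zero-phase filtering avoids group delay that would shift trial
#' onsets.
#'
#' @param x Numeric matrix (channels x samples) or vector.
#' @param rate Sampling rate in Hz.
#' @param low,high Band edges in Hz (defaults 20 and 400, the hardware
#'   band of the recording chain being emulated).
#' @param order Butterworth order per band edge (default 4).
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, rate, low = 20, high = 400, order = 4) {
  if (!(low > 0 && low < high && high < rate / 2)) {
    stop("band edges must satisfy 0 < low < high < rate/2", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  if (is.matrix(x)) {
    t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Full-wave rectification
#'
#' @param x Numeric vector/matrix with finite values.
#' @return `abs(x)`.
#' @export
rectify <- function(x) {
  if (any(!is.finite(x))) stop("signal contains non-finite values",
                               call. = FALSE)
  abs(x)
}

#' ARV envelope by non-overlapping bin means
#'
#' Downsamples a rectified signal to `target` Hz by averaging consecutive
#' non-overlapping bins of `rate / target` samples (the average rectified
#' value estimator). Trailing samples that do not fill a bin are dropped.
#'
#' @param x Nonnegative numeric matrix (channels x samples) or vector.
#' @param rate Input sampling rate in Hz; must be divisible by `target`.
#' @param target Output rate in Hz (default 10).
#' @param method `"mean"` (ARV, default) or `"rms"`.
#' @return Envelope at `target` Hz (same orientation as `x`).
#' @export
downsample_envelope <- function(x, rate, target = 10,
                                method = c("mean", "rms")) {
  method <- match.arg(method)
  factor <- rate / target
  if (factor != round(factor)) {
    stop("rate (", rate, ") must be divisible by target (", target, ")",
         call. = FALSE)
  }
  factor <- as.integer(factor)
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  n_out <- floor(ncol(x) / factor)
  x <- x[, seq_len(n_out * factor), drop = FALSE]
  out <- vapply(seq_len(n_out), function(j) {
    cols <- ((j - 1) * factor + 1):(j * factor)
    if (method == "mean") {
      rowMeans(x[, cols, drop = FALSE])
    } else {
      sqrt(rowMeans(x[, cols, drop = FALSE]^2))
    }
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x))
  if (vec) out[1, ] else out
}

#' Cut a continuous envelope into trial epochs
#'
#' Extracts, for every marker, the 55-point window covering 500 ms before
#' stimulus onset (5 baseline points) and 5000 ms of action period (50
#' points), half-open on the right.
#'
#' @param env Envelope matrix (channels x envelope samples) at `env_rate`.
#' @param markers Data frame with `onset_sample` (0-based, raw-rate) and
#'   `condition` columns.
#' @param env_rate Envelope rate in Hz (default 10).
#' @param raw_rate Sampling rate the marker onsets refer to (default 1000).
#' @param participant_id Stored in the result.
#' @param pre_s,post_s Window extent in seconds (defaults 0.5 and 5).
#' @return An [emg_epochs()] object (trials x channels x 55).
#' @export
epoch_envelope <- function(env, markers, env_rate = 10, raw_rate = 1000,
                           participant_id = "P01",
                           pre_s = 0.5, post_s = 5) {
  if (!is.matrix(env)) env <- matrix(env, nrow = 1)
  bin <- raw_rate / env_rate
  n_baseline <- round(pre_s * env_rate)
  n_stimulus <- round(post_s * env_rate)
  pts <- n_baseline + n_stimulus
  n_trials <- nrow(markers)
  dat <- array(0, c(n_trials, nrow(env), pts))
  for (tr in seq_len(n_trials)) {
    start <- floor((markers$onset_sample[tr] - pre_s * raw_rate) / bin)
    if (start < 0 || start + pts > ncol(env)) {
      stop("trial ", tr, ": epoch window [", start, ", ", start + pts,
           ") outside envelope of length ", ncol(env), call. = FALSE)
    }
    dat[tr, , ] <- env[, (start + 1):(start + pts)]
  }
  emg_epochs(participant_id, dat, as.character(markers$condition),
             envelope_rate = env_rate, n_baseline = n_baseline,
             n_stimulus = n_stimulus,
             channel_names = if (is.null(rownames(env))) muscle_names()
                             else rownames(env))
}

#' Concatenate trial epochs into one channels x timepoints matrix
#'
#' Lays trials end to end in recorded order, the form fed to
#' per-participant ICA. The returned index map inverts the operation via
#' [split_trials()].
#'
#' @param ep An [emg_epochs()] object.
#' @return List with `matrix` (channels x trials*timepoints) and
#'   `trial_index` (integer vector mapping each column to its trial).
#' @export
concatenate_trials <- function(ep) {
  stopifnot(inherits(ep, "emg_epochs"))
  d <- dim(ep$data)
  mat <- matrix(0, d[2], d[1] * d[3])
  for (tr in seq_len(d[1])) {
    mat[, ((tr - 1) * d[3] + 1):(tr * d[3])] <- ep$data[tr, , ]
  }
  list(matrix = mat, trial_index = rep(seq_len(d[1]), each = d[3]))
}

#' Split a concatenated matrix back into trial epochs
#'
#' Inverse of [concatenate_trials()]; `template` supplies trial structure
#' and metadata.
#'
#' @param mat Channels x (trials * timepoints) matrix.
#' @param template The [emg_epochs()] the matrix was concatenated from.
#' @param version Version tag of the resulting epochs (default
#'   `"reconstructed"`, which permits negative values).
#' @return An [emg_epochs()] object shaped like `template`.
#' @export
split_trials <- function(mat, template,
                         version = c("reconstructed", "original")) {
  version <- match.arg(version)
  d <- dim(template$data)
  stopifnot(ncol(mat) == d[1] * d[3], nrow(mat) == d[2])
  dat <- array(0, d)
  for (tr in seq_len(d[1])) {
    dat[tr, , ] <- mat[, ((tr - 1) * d[3] + 1):(tr * d[3])]
  }
  emg_epochs(template$participant_id, dat, template$conditions,
             envelope_rate = template$envelope_rate,
             n_baseline = template$n_baseline,
             n_stimulus = template$n_stimulus,
             channel_names = template$channel_names,
             version = version)
}

#' Preprocess a raw recording into envelope epochs
#'
#' Runs the full chain bandpass -> rectify -> ARV downsample -> epoch.
#'
#' @param rec An [emg_recording()].
#' @param low,high Band edges in Hz (defaults 20, 400).
#' @param target Envelope rate in Hz (default 10).
#' @param method Envelope estimator, `"mean"` (ARV) or `"rms"`.
#' @return An [emg_epochs()] object.
#' @export
preprocess_recording <- function(rec, low = 20, high = 400, target = 10,
                                 method = "mean") {
  validate_recording(rec)
  filt <- bandpass(rec$signal, rec$sampling_rate, low, high)
  env <- downsample_envelope(rectify(filt), rec$sampling_rate, target,
                             method = method)
  rownames(env) <- rec$channel_names
  epoch_envelope(env, rec$markers, env_rate = target,
                 raw_rate = rec$sampling_rate,
                 participant_id = rec$participant_id)
}
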