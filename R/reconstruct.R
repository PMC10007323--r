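# Component selection, partial back-projection and condition summaries.

#' Select the two target components
#'
#' Picks the component holding the highest variance share on the first
#' target channel (corrugator by default) and the component holding the
#' highest share on the second (zygomatic). If both rows pick the same
#' component, the second target falls back to its next-best distinct
#' component. Ties break toward the lower component index.
#'
#' @param V Variance-share matrix (channels x components) from
#'   [variance_shares()], or an `emg_ica` object.
#' @param targets Two distinct channel indices or names (default
#'   `c("corrugator", "zygomatic")`).
#' @param channel_names Channel labels for name lookup (default
#'   [muscle_names()]).
#' @return Integer vector of two distinct component indices (first target
#'   first).
#' @export
select_target_components <- function(V, targets = c("corrugator", "zygomatic"),
                                     channel_names = muscle_names()) {
  if (inherits(V, "emg_ica")) V <- V$V
  if (ncol(V) < 2) stop("need at least 2 components", call. = FALSE)
  if (is.character(targets)) {
    targets <- match(targets, channel_names)
    if (any(is.na(targets))) stop("unknown target channel", call. = FALSE)
  }
  stopifnot(length(targets) == 2, targets[1] != targets[2])
  k1 <- which.max(V[targets[1], ])           # which.max takes lowest on ties
  ord2 <- order(V[targets[2], ], decreasing = TRUE)
  k2 <- ord2[ord2 != k1][1]
  c(k1, k2)
}

#' Partial back-projection reconstruction
#'
#' Reconstructs the channel signals from a subset of components:
#' `A_hat[, keep] %*% S[keep, ] + channel means`. Keeping all components
#' reproduces the decomposed input (to numerical precision); keeping the
#' two target components removes the variance carried by the discarded
#' (mouth-muscle) components from every channel.
#'
#' @param dec An `emg_ica` decomposition.
#' @param keep Integer vector of component indices to retain. An empty
#'   `keep` is allowed (returns the channel-mean matrix) but flagged with
#'   a warning as degenerate.
#' @return Channels x timepoints reconstructed matrix (may contain
#'   negative values; back-projection is unconstrained).
#' @export
partial_reconstruct <- function(dec, keep) {
  stopifnot(inherits(dec, "emg_ica"))
  n_comp <- nrow(dec$S)
  if (length(keep) == 0) {
    warning("empty component set: reconstruction degenerates to channel means",
            call. = FALSE)
    return(matrix(dec$means, length(dec$means), ncol(dec$S)))
  }
  if (any(keep < 1 | keep > n_comp)) {
    stop("keep indices must lie in 1..", n_comp, call. = FALSE)
  }
  dec$A_hat[, keep, drop = FALSE] %*% dec$S[keep, , drop = FALSE] + dec$means
}

#' Per-condition scalar amplitudes for original and reconstructed epochs
#'
#' For every trial and channel the envelope is baseline-corrected by
#' subtracting the mean of the pre-stimulus points, then averaged across
#' the stimulus points; the per-trial scalars are averaged within each
#' condition. Produced for both signal versions when `ep_reconstructed`
#' is supplied.
#'
#' @param ep_original Original [emg_epochs()].
#' @param ep_reconstructed Optional reconstructed epochs with matched
#'   shape and trial order.
#' @return Data frame with columns `participant`, `condition`, `channel`,
#'   `version`, `mean_amplitude` (one row per condition x channel x
#'   version).
#' @export
summarize_conditions <- function(ep_original, ep_reconstructed = NULL) {
  stopifnot(inherits(ep_original, "emg_epochs"))
  if (!is.null(ep_reconstructed)) {
    stopifnot(inherits(ep_reconstructed, "emg_epochs"),
              identical(dim(ep_original$data), dim(ep_reconstructed$data)),
              identical(ep_original$conditions, ep_reconstructed$conditions))
  }
  one_version <- function(ep, version) {
    d <- dim(ep$data)
    base_idx <- seq_len(ep$n_baseline)
    stim_idx <- ep$n_baseline + seq_len(ep$n_stimulus)
    # trials x channels matrix of baseline-corrected stimulus means
    trial_amp <- apply(ep$data[, , stim_idx, drop = FALSE], c(1, 2), mean) -
      apply(ep$data[, , base_idx, drop = FALSE], c(1, 2), mean)
    conds <- unique(ep$conditions)
    out <- expand.grid(condition = conds,
                       channel = ep$channel_names,
                       stringsAsFactors = FALSE)
    out$mean_amplitude <- mapply(function(cond, ch) {
      rows <- which(ep$conditions == cond)
      if (length(rows) == 0) stop("condition with zero trials: ", cond,
                                  call. = FALSE)
      mean(trial_amp[rows, match(ch, ep$channel_names)])
    }, out$condition, out$channel)
    data.frame(participant = ep$participant_id, condition = out$condition,
               channel = out$channel, version = version,
               mean_amplitude = out$mean_amplitude,
               stringsAsFactors = FALSE)
  }
  res <- one_version(ep_original, "original")
  if (!is.null(ep_reconstructed)) {
    res <- rbind(res, one_version(ep_reconstructed, "reconstructed"))
  }
  rownames(res) <- NULL
  res
}
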