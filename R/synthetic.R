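# Synthetic facial-EMG cohort: known sources, known crosstalk mixing.
#
# The simulator emulates the study design the pipeline is built for:
# 29 participants, 8 facial-action conditions x 8 trials, 4 channels at
# 1000 Hz band-limited to 20-400 Hz, with instantaneous (zero-lag)
# volume-conduction crosstalk whose strength falls off with the square of
# the inter-electrode distance.

#' Electrode-site geometry
#'
#' Pairwise distances (cm) between the four electrode sites. The default
#' table encodes the facial layout that drives the crosstalk asymmetry:
#' the mouth muscles (masseter, suprahyoid) are close to the zygomatic
#' major site and far from the corrugator site on the brow.
#'
#' @param distances Optional 4x4 symmetric numeric matrix (cm, zero
#'   diagonal, positive off-diagonals) with rows/columns in
#'   [muscle_names()] order.
#' @return A symmetric distance matrix with dimnames.
#' @export
muscle_geometry <- function(distances = NULL) {
  m <- muscle_names()
  if (is.null(distances)) {
    distances <- matrix(0, 4, 4, dimnames = list(m, m))
    d <- function(a, b, v) {
      distances[a, b] <<- v
      distances[b, a] <<- v
    }
    d("corrugator", "zygomatic", 7)
    d("corrugator", "masseter", 10)
    d("corrugator", "suprahyoid", 13)
    d("zygomatic", "masseter", 3)
    d("zygomatic", "suprahyoid", 5)
    d("masseter", "suprahyoid", 6)
  }
  if (!isSymmetric(unname(distances)) || any(diag(distances) != 0)) {
    stop("geometry must be symmetric with zero diagonal", call. = FALSE)
  }
  off <- distances[row(distances) != col(distances)]
  if (any(off <= 0)) {
    stop("off-diagonal distances must be positive", call. = FALSE)
  }
  dimnames(distances) <- list(m, m)
  distances
}

#' Distance-dependent crosstalk mixing matrix
#'
#' Builds the channels x sources mixing matrix `A` from electrode geometry
#' under an inverse-square attenuation law:
#' `A[c, s] = 1` on the diagonal and
#' `min(1, (d0 / distance[c, s])^2) * gain[c, s]` off it.
#'
#' @param geometry Distance matrix from [muscle_geometry()].
#' @param d0 Reference distance (cm) at which a source would reach a
#'   non-target electrode at full amplitude; default 1.6.
#' @param gain Scalar or 4x4 matrix of per-pair multipliers (default 1).
#' @return A 4x4 mixing matrix with unit diagonal, off-diagonals in
#'   `[0, 1)`, and finite condition number.
#' @export
default_mixing <- function(geometry = muscle_geometry(), d0 = 1.6, gain = 1) {
  stopifnot(d0 > 0)
  if (length(gain) == 1) gain <- matrix(gain, nrow(geometry), ncol(geometry))
  A <- pmin(1, (d0 / geometry)^2) * gain
  diag(A) <- 1
  dimnames(A) <- dimnames(geometry)
  off <- A[row(A) != col(A)]
  if (any(off < 0) || any(off >= 1)) {
    stop("off-diagonal mixing entries must lie in [0, 1)", call. = FALSE)
  }
  if (!is.finite(kappa(A)) || abs(det(A)) < 1e-12) {
    stop("mixing matrix is not invertible", call. = FALSE)
  }
  A
}

#' Source activation specification for the simulator
#'
#' Describes how each muscle's EMG envelope behaves: a tonic resting level
#' with slow multiplicative drift, plus condition-dependent activation
#' bursts riding on a band-limited (20-400 Hz) Gaussian carrier. Chewing
#' and speaking drive the masseter and suprahyoid rhythmically, in
#' antiphase (jaw closers and openers alternate); speaking is faster and
#' weaker than chewing. Sustained holds (frowning, smiling) wax and wane
#' slowly rather than staying flat, rhythm phase is redrawn on every trial
#' (actions are not locked to stimulus onset), and per-trial amplitudes
#' jitter lognormally - voluntary expressive intensity varies widely from
#' trial to trial. Combination conditions take the union (pointwise
#' maximum) of their parts' activations.
#'
#' All amplitudes are unitless (microvolt-like); the analysis is
#' scale-invariant through baseline correction.
#'
#' @param tonic Resting envelope level per muscle (scalar or length-4).
#' @param actions Named list mapping each elementary action (`frown`,
#'   `smile`, `chew`, `speak`) to a named list of per-muscle entries
#'   `list(amp =, freq =, phase =, depth =)`: the activation is modulated
#'   by `(1 - depth) + depth * sin(2 * pi * freq * t + phase + trial
#'   phase)`; `freq = NA` means constant (unmodulated) activation,
#'   otherwise `freq` must lie in (0.5, 10) Hz and `depth` in `[0, 1]`.
#' @param onset_ramp_ms Linear rise time of activation after stimulus
#'   onset (default 500 ms).
#' @param offset_decay_ms Exponential decay time constant after the action
#'   window (default 100 ms).
#' @param sensor_noise_sd Additive band-limited sensor noise SD (default
#'   0.3).
#' @param drift_sd Log-scale SD of the slow (< `drift_cutoff_hz`) tonic
#'   drift emulating baseline wander (default 0.1).
#' @param drift_cutoff_hz Low-pass cutoff of the drift process (default
#'   0.2 Hz).
#' @param trial_jitter_sdlog Lognormal SD of per-trial activation
#'   amplitude jitter (default 0.55).
#' @return A list of class `emg_source_spec`.
#' @export
source_spec <- function(tonic = 1,
                        actions = NULL,
                        onset_ramp_ms = 500,
                        offset_decay_ms = 100,
                        sensor_noise_sd = 0.3,
                        drift_sd = 0.1,
                        drift_cutoff_hz = 0.2,
                        trial_jitter_sdlog = 0.55) {
  m <- muscle_names()
  if (length(tonic) == 1) tonic <- rep(tonic, 4)
  names(tonic) <- m
  if (is.null(actions)) {
    actions <- list(
      frown = list(corrugator = list(amp = 3, freq = 0.6, phase = 0,
                                     depth = 0.4)),
      smile = list(zygomatic = list(amp = 3, freq = 0.6, phase = 0,
                                    depth = 0.4)),
      chew = list(masseter = list(amp = 4, freq = 1.5, phase = 0,
                                  depth = 0.5),
                  suprahyoid = list(amp = 3, freq = 1.5, phase = pi,
                                    depth = 0.5)),
      speak = list(masseter = list(amp = 2, freq = 3, phase = 0,
                                   depth = 0.5),
                   suprahyoid = list(amp = 2.5, freq = 3, phase = pi,
                                     depth = 0.5)))
  }
  spec <- structure(
    list(tonic = tonic, actions = actions,
         onset_ramp_ms = onset_ramp_ms, offset_decay_ms = offset_decay_ms,
         sensor_noise_sd = sensor_noise_sd, drift_sd = drift_sd,
         drift_cutoff_hz = drift_cutoff_hz,
         trial_jitter_sdlog = trial_jitter_sdlog),
    class = "emg_source_spec")
  validate_source_spec(spec)
}

validate_source_spec <- function(spec) {
  if (any(spec$tonic < 0) || spec$sensor_noise_sd < 0) {
    stop("amplitudes must be nonnegative", call. = FALSE)
  }
  base_actions <- c("frown", "smile", "chew", "speak")
  if (!all(names(spec$actions) %in% base_actions)) {
    stop("actions must be a subset of: ",
         paste(base_actions, collapse = ", "), call. = FALSE)
  }
  for (act in spec$actions) {
    for (mu in names(act)) {
      if (!mu %in% muscle_names()) {
        stop("unknown muscle in action spec: ", mu, call. = FALSE)
      }
      e <- act[[mu]]
      if (e$amp < 0) stop("activation amplitudes must be >= 0", call. = FALSE)
      if (!is.na(e$freq) && (e$freq <= 0.5 || e$freq >= 10)) {
        stop("rhythmic frequency must lie in (0.5, 10) Hz", call. = FALSE)
      }
      depth <- e$depth %||% 0.5
      if (depth < 0 || depth > 1) {
        stop("modulation depth must lie in [0, 1]", call. = FALSE)
      }
    }
  }
  # every condition resolves through its parts, possibly to zero activation
  for (cond in condition_labels()) condition_parts(cond)
  spec
}

# Activation envelope added above tonic for one condition, as a
# muscles x timepoints matrix. `t_rel` is time (s) relative to stimulus
# onset; the action window is [0, 5); before onset the activation is zero,
# after 5 s it decays exponentially. `trial_phase` shifts every rhythmic
# entry of the trial jointly (rhythms are not stimulus-locked but phase
# relations between muscles are preserved).
condition_activation <- function(spec, condition, t_rel,
                                 amp_scale = NULL, trial_phase = 0) {
  m <- muscle_names()
  env <- matrix(0, length(m), length(t_rel), dimnames = list(m, NULL))
  ramp <- pmax(0, pmin(1, t_rel / (spec$onset_ramp_ms / 1000)))
  decay <- ifelse(t_rel >= 5,
                  exp(-(t_rel - 5) / (spec$offset_decay_ms / 1000)), 1)
  gate <- ifelse(t_rel < 0, 0, ramp * decay)
  for (part in condition_parts(condition)) {
    act <- spec$actions[[part]]
    if (is.null(act)) next
    for (mu in names(act)) {
      e <- act[[mu]]
      amp <- e$amp * (amp_scale[[mu]] %||% 1)
      mod <- if (is.na(e$freq)) rep(1, length(t_rel)) else {
        depth <- e$depth %||% 0.5
        (1 - depth) + depth * sin(2 * pi * e$freq * pmax(t_rel, 0) -
                                    pi / 2 + e$phase + trial_phase)
      }
      env[mu, ] <- pmax(env[mu, ], amp * gate * mod)
    }
  }
  env
}

# Slow multiplicative drift multiplier, one row per muscle.
make_drift <- function(spec, n_muscles, n, rate) {
  if (spec$drift_sd <= 0) return(matrix(1, n_muscles, n))
  bf <- signal::butter(2, min(0.99, spec$drift_cutoff_hz / (rate / 2)),
                       type = "low")
  t(vapply(seq_len(n_muscles), function(i) {
    w <- signal::filtfilt(bf, rnorm(n))
    s <- sd(w)
    if (s < .Machine$double.eps) return(rep(1, n))
    exp(w / s * spec$drift_sd)
  }, numeric(n)))
}

# Unit-SD band-limited (20-400 Hz) Gaussian noise rows.
make_carriers <- function(n_rows, n, rate, low = 20, high = 400) {
  bf <- signal::butter(4, c(low, high) / (rate / 2), type = "pass")
  t(vapply(seq_len(n_rows), function(i) {
    x <- signal::filtfilt(bf, rnorm(n))
    x / sd(x)
  }, numeric(n)))
}

# Blocked pseudorandom trial order: every block of 8 trials contains each
# condition once.
make_design <- function(trials_per_condition = 8) {
  unlist(lapply(seq_len(trials_per_condition),
                function(b) sample(condition_labels())))
}

check_design <- function(design, trials_per_condition) {
  assert_condition(design)
  tab <- table(factor(design, levels = condition_labels()))
  if (!all(tab == trials_per_condition)) {
    stop("trial design must contain exactly ", trials_per_condition,
         " trials of each of the 8 conditions", call. = FALSE)
  }
  design
}

#' Simulate one participant's recording with known ground truth
#'
#' Generates per-muscle source envelopes (tonic drift + condition-dependent
#' activation), multiplies them with independent band-limited carriers,
#' mixes the raw signals through the crosstalk matrix and adds band-limited
#' sensor noise. Trials are laid out back-to-back in 6 s slots (0.5 s
#' baseline + 5 s action + 0.5 s rest) with the marker at each action
#' onset.
#'
#' With `envelope_domain = TRUE` the generative model is applied directly
#' to nonnegative 10 Hz envelopes (observed = `A %*% sources` + noise),
#' i.e. the exact linear-mixing model that ICA assumes; this mode returns
#' ready-made [emg_epochs()] and is intended for algorithm-correctness
#' tests and fast large-replicate studies.
#'
#' @param spec A [source_spec()].
#' @param mix Mixing matrix from [default_mixing()].
#' @param seed RNG seed (required; the simulation is deterministic given
#'   it).
#' @param design Optional explicit condition sequence (length 64 with 8
#'   trials per condition); default: blocked pseudorandom order.
#' @param participant_id Identifier stored in the outputs.
#' @param trials_per_condition Trials per condition (default 8).
#' @param envelope_domain Generate at the envelope level instead of the
#'   raw-signal level (default `FALSE`).
#' @param sampling_rate Raw sampling rate in Hz (default 1000).
#' @return A list with elements `truth` (source envelopes, mixing matrix,
#'   seed) and either `recording` (raw mode) or `epochs` (envelope mode).
#' @export
simulate_participant <- function(spec = source_spec(),
                                 mix = default_mixing(),
                                 seed,
                                 design = NULL,
                                 participant_id = "P01",
                                 trials_per_condition = 8,
                                 envelope_domain = FALSE,
                                 sampling_rate = 1000) {
  validate_source_spec(spec)
  with_seed(seed, {
    design <- if (is.null(design)) make_design(trials_per_condition) else
      check_design(design, trials_per_condition)
    n_trials <- length(design)
    jitter <- if (spec$trial_jitter_sdlog > 0) {
      matrix(rlnorm(n_trials * 4, 0, spec$trial_jitter_sdlog), n_trials, 4,
             dimnames = list(NULL, muscle_names()))
    } else {
      matrix(1, n_trials, 4, dimnames = list(NULL, muscle_names()))
    }
    phases <- runif(n_trials, 0, 2 * pi)
    if (envelope_domain) {
      simulate_envelope_domain(spec, mix, design, jitter, phases,
                               participant_id)
    } else {
      simulate_raw_domain(spec, mix, design, jitter, phases,
                          participant_id, sampling_rate, seed)
    }
  })
}

simulate_raw_domain <- function(spec, mix, design, jitter, phases,
                                participant_id, rate, seed) {
  n_trials <- length(design)
  slot <- 6 * rate                      # 0.5 s pre + 5 s action + 0.5 s rest
  n <- n_trials * slot
  onsets <- (seq_len(n_trials) - 1) * slot + round(0.5 * rate)

  env <- spec$tonic * make_drift(spec, 4, n, rate)
  t_slot <- (seq_len(slot) - 1) / rate - 0.5   # time rel. to onset, one slot
  for (tr in seq_len(n_trials)) {
    idx <- ((tr - 1) * slot + 1):(tr * slot)
    act <- condition_activation(spec, design[tr], t_slot,
                                amp_scale = as.list(jitter[tr, ]),
                                trial_phase = phases[tr])
    env[, idx] <- env[, idx] + act
  }

  carriers <- make_carriers(4, n, rate)
  sources <- env * carriers
  observed <- mix %*% sources
  if (spec$sensor_noise_sd > 0) {
    observed <- observed + spec$sensor_noise_sd * make_carriers(4, n, rate)
  }
  dimnames(observed) <- NULL

  rec <- emg_recording(participant_id, observed,
                       data.frame(onset_sample = onsets,
                                  condition = design),
                       sampling_rate = rate)
  truth <- structure(
    list(envelopes = env, mixing = mix, seed = seed, rate = rate,
         design = design, envelope_domain = FALSE),
    class = "emg_truth")
  list(recording = rec, truth = truth)
}

# ARV estimator statistics for |N(0, s)| averaged over `bin` samples:
# mean 0.798 s, sd 0.603 s / sqrt(bin).
ARV_MEAN_FACTOR <- sqrt(2 / pi)
ARV_SD_FACTOR <- sqrt(1 - 2 / pi)

simulate_envelope_domain <- function(spec, mix, design, jitter, phases,
                                     participant_id, env_rate = 10,
                                     bin = 100) {
  n_trials <- length(design)
  pts <- 55
  n <- n_trials * pts
  env <- spec$tonic * make_drift(spec, 4, n, env_rate)
  t_trial <- ((seq_len(pts) - 0.5) / env_rate) - 0.5  # bin centres
  for (tr in seq_len(n_trials)) {
    idx <- ((tr - 1) * pts + 1):(tr * pts)
    env[, idx] <- env[, idx] +
      condition_activation(spec, design[tr], t_trial,
                           amp_scale = as.list(jitter[tr, ]),
                           trial_phase = phases[tr])
  }
  # per-bin ARV sampling jitter is part of the source envelope
  rel_sd <- ARV_SD_FACTOR / sqrt(bin) / ARV_MEAN_FACTOR
  sources <- pmax(env * (1 + rel_sd * matrix(rnorm(4 * n), 4, n)), 0)
  observed <- mix %*% sources
  if (spec$sensor_noise_sd > 0) {
    observed <- observed +
      spec$sensor_noise_sd * ARV_SD_FACTOR / sqrt(bin) *
        matrix(rnorm(4 * n), 4, n)
  }
  observed <- pmax(observed, 0)
  dat <- array(0, c(n_trials, 4, pts))
  for (tr in seq_len(n_trials)) {
    dat[tr, , ] <- observed[, ((tr - 1) * pts + 1):(tr * pts)]
  }
  ep <- emg_epochs(participant_id, dat, design)
  truth <- structure(
    list(envelopes = sources, mixing = mix, seed = NA, rate = env_rate,
         design = design, envelope_domain = TRUE),
    class = "emg_truth")
  list(epochs = ep, truth = truth)
}

#' Simulate a cohort of participants
#'
#' Derives an independent seed per participant from `master_seed` and
#' applies between-participant variation as a lognormal scaling of each
#' muscle's activation amplitudes (electrode placement and physiology
#' differ across people).
#'
#' @param n_participants Number of participants (>= 2; default 29, the
#'   cohort size the pipeline's power analysis motivates).
#' @param spec,mix,envelope_domain,trials_per_condition Passed to
#'   [simulate_participant()].
#' @param master_seed Seed from which all per-participant seeds derive.
#' @param participant_sdlog Lognormal SD of the per-muscle amplitude
#'   scaling across participants (default 0.4; 0 disables it).
#' @return List of `n_participants` results from
#'   [simulate_participant()].
#' @export
simulate_cohort <- function(n_participants = 29,
                            spec = source_spec(),
                            mix = default_mixing(),
                            master_seed = 1,
                            participant_sdlog = 0.4,
                            trials_per_condition = 8,
                            envelope_domain = FALSE) {
  if (n_participants < 2) {
    stop("n_participants must be >= 2", call. = FALSE)
  }
  seeds <- derive_seeds(master_seed, 2 * n_participants)
  lapply(seq_len(n_participants), function(i) {
    spec_i <- spec
    if (participant_sdlog > 0) {
      mult <- with_seed(seeds[n_participants + i],
                        rlnorm(4, 0, participant_sdlog))
      names(mult) <- muscle_names()
      for (a in names(spec_i$actions)) {
        for (mu in names(spec_i$actions[[a]])) {
          spec_i$actions[[a]][[mu]]$amp <-
            spec_i$actions[[a]][[mu]]$amp * mult[[mu]]
        }
      }
    }
    simulate_participant(spec_i, mix, seed = seeds[i],
                         participant_id = sprintf("P%02d", i),
                         trials_per_condition = trials_per_condition,
                         envelope_domain = envelope_domain)
  })
}

#' Ground-truth source envelopes on the concatenated 10 Hz epoch grid
#'
#' Converts a raw-mode ground truth to the same sources x (trials * 55)
#' matrix that the preprocessing pipeline produces for the observed
#' channels, enabling component-to-source matching.
#'
#' @param truth `emg_truth` from [simulate_participant()].
#' @param rec The paired [emg_recording()] (raw mode only; ignored in
#'   envelope mode).
#' @return Sources x timepoints matrix.
#' @export
truth_concatenated <- function(truth, rec = NULL) {
  if (isTRUE(truth$envelope_domain)) return(truth$envelopes)
  stopifnot(inherits(rec, "emg_recording"))
  env10 <- downsample_envelope(truth$envelopes, truth$rate, 10)
  ep <- epoch_envelope(env10, rec$markers, raw_rate = truth$rate)
  concatenate_trials(ep)$matrix
}
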