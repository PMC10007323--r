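# Shared fixtures, built in code.

# Minimal valid recording: `n_trials` markers at 6 s spacing over low-level
# noise (deterministic given seed).
tiny_recording <- function(n_trials = 3, rate = 1000, seed = 123,
                           participant_id = "T01") {
  n <- n_trials * 6 * rate
  sig <- emgica:::with_seed(seed,
                            matrix(rnorm(4 * n, sd = 0.1), nrow = 4))
  onsets <- (seq_len(n_trials) - 1) * 6 * rate + round(0.5 * rate)
  emg_recording(participant_id, sig,
                data.frame(onset_sample = onsets,
                           condition = condition_labels()[seq_len(n_trials)]),
                sampling_rate = rate)
}

# Null source specification: tonic noise only, no action-related activation.
null_spec <- function() {
  source_spec(actions = list(frown = list(), smile = list(),
                             chew = list(), speak = list()))
}

# Laplacian-like super-Gaussian sources, deterministic given seed.
laplacian_sources <- function(n_sources, n_points, seed) {
  emgica:::with_seed(seed, {
    matrix(stats::rexp(n_sources * n_points) *
             sample(c(-1, 1), n_sources * n_points, replace = TRUE),
           nrow = n_sources)
  })
}

# The worked 2 x 2 mixture used across ICA tests.
two_source_mixture <- function(n_points = 10000, seed = 5) {
  S <- laplacian_sources(2, n_points, seed)
  A <- matrix(c(1, 0.2, 0.3, 1), 2)
  list(S = S, A = A, X = A %*% S)
}
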