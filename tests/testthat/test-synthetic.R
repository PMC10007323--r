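test_that("mixing matrix follows the inverse-square distance rule", {
  # no volume conduction at infinite distance
  far <- matrix(1e9, 4, 4); diag(far) <- 0
  expect_equal(unname(default_mixing(muscle_geometry(far))), diag(4),
               tolerance = 1e-12)

  # at the reference distance the entry equals the pair gain
  g <- matrix(1.6, 4, 4); diag(g) <- 0
  A <- default_mixing(muscle_geometry(g), d0 = 1.6, gain = 0.3)
  expect_equal(unname(A[1, 2]), 0.3, tolerance = 1e-12)

  # hand-computed (d0/d)^2 entries for the worked geometry
  m <- muscle_names()
  geo <- matrix(1e3, 4, 4, dimnames = list(m, m)); diag(geo) <- 0
  geo["zygomatic", "masseter"] <- geo["masseter", "zygomatic"] <- 3
  geo["zygomatic", "suprahyoid"] <- geo["suprahyoid", "zygomatic"] <- 5
  geo["corrugator", "masseter"] <- geo["masseter", "corrugator"] <- 9
  A <- default_mixing(muscle_geometry(geo), d0 = 1.6)
  expect_equal(unname(A["zygomatic", "masseter"]), (1.6 / 3)^2,
               tolerance = 1e-12)   # ~0.284
  expect_equal(unname(A["corrugator", "masseter"]), (1.6 / 9)^2,
               tolerance = 1e-12)   # ~0.032
})

test_that("default geometry reproduces the facial crosstalk asymmetry", {
  A <- default_mixing()
  off <- A[row(A) != col(A)]
  # mouth-muscle -> zygomatic entries are the largest off-diagonals
  expect_equal(max(off), A["zygomatic", "masseter"])
  expect_gt(A["zygomatic", "suprahyoid"],
            max(A["corrugator", c("masseter", "suprahyoid")]))
  # corrugator couples weakest to the mouth muscles
  expect_equal(min(off), A["corrugator", "suprahyoid"])
  expect_true(all(diag(A) == 1))
  expect_true(all(off >= 0 & off < 1))
})

test_that("degenerate geometry is rejected", {
  bad <- matrix(2, 4, 4); diag(bad) <- 0
  bad[1, 2] <- 3
  expect_error(muscle_geometry(bad), "symmetric")
  neg <- matrix(-1, 4, 4); diag(neg) <- 0
  expect_error(muscle_geometry(neg), "positive")
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_participant(seed = 9)
  b <- simulate_participant(seed = 9)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$recording$markers, b$recording$markers)
  expect_identical(a$truth$envelopes, b$truth$envelopes)
  c <- simulate_participant(seed = 10)
  expect_false(identical(a$recording$signal, c$recording$signal))
})

test_that("silent specification produces an all-zero recording", {
  sp <- null_spec()
  sp$tonic[] <- 0
  sp$sensor_noise_sd <- 0
  sp$drift_sd <- 0
  sim <- simulate_participant(sp, seed = 4)
  expect_equal(max(abs(sim$recording$signal)), 0)
  expect_equal(max(abs(sim$truth$envelopes)), 0)
})

test_that("every participant gets exactly 8 trials per condition", {
  sim <- simulate_participant(seed = 15)
  tab <- table(sim$recording$markers$condition)
  expect_equal(sort(names(tab)), sort(condition_labels()))
  expect_true(all(tab == 8))
  expect_error(
    simulate_participant(seed = 1, design = rep("chew", 64)),
    "8 trials")
})

test_that("chewing leaks into the observed zygomatic channel but not its source", {
  sim <- simulate_participant(seed = 1)
  rec <- sim$recording
  zyg <- match("zygomatic", rec$channel_names)
  chew_on <- rec$markers$onset_sample[rec$markers$condition == "chew"]
  stim_rms <- base_rms <- src_stim <- src_base <- numeric(0)
  for (on in chew_on) {
    stim_idx <- (on + 1):(on + 5000)
    base_idx <- (on - 499):on
    stim_rms <- c(stim_rms, sqrt(mean(rec$signal[zyg, stim_idx]^2)))
    base_rms <- c(base_rms, sqrt(mean(rec$signal[zyg, base_idx]^2)))
    src_stim <- c(src_stim, mean(sim$truth$envelopes[zyg, stim_idx]))
    src_base <- c(src_base, mean(sim$truth$envelopes[zyg, base_idx]))
  }
  # ground-truth zygomatic source stays at tonic baseline during chewing
  expect_equal(mean(src_stim) / mean(src_base), 1, tolerance = 0.1)
  # ... while the observed channel's RMS rises above its pre-stimulus RMS
  expect_gt(mean(stim_rms) / mean(base_rms), 1.1)
})

test_that("envelope-domain mixing is exactly conserved without sensor noise", {
  sp <- source_spec(sensor_noise_sd = 0)
  sim <- simulate_participant(sp, seed = 3, envelope_domain = TRUE)
  obs <- concatenate_trials(sim$epochs)$matrix
  recon <- sim$truth$mixing %*% sim$truth$envelopes
  expect_lt(max(abs(obs - recon)) / max(abs(obs)), 1e-9)
})

test_that("distinct source envelopes stay nearly uncorrelated at defaults", {
  for (s in c(11, 22)) {
    sim <- simulate_participant(seed = s)
    cm <- cor(t(sim$truth$envelopes))
    expect_lt(max(abs(cm[row(cm) != col(cm)])), 0.3)
  }
})

test_that("cohort generation is reproducible and varies across participants", {
  co <- simulate_cohort(n_participants = 2, master_seed = 5,
                        envelope_domain = TRUE)
  expect_length(co, 2)
  co2 <- simulate_cohort(n_participants = 2, master_seed = 5,
                         envelope_domain = TRUE)
  expect_identical(co[[1]]$epochs$data, co2[[1]]$epochs$data)
  expect_false(identical(co[[1]]$epochs$data, co[[2]]$epochs$data))
  expect_error(simulate_cohort(n_participants = 1), ">= 2")
})

test_that("raw cohort recordings carry 64 markers each", {
  co <- simulate_cohort(n_participants = 2, master_seed = 8)
  for (p in co) {
    expect_equal(nrow(p$recording$markers), 64)
    validate_recording <- emgica:::validate_recording
    expect_silent(validate_recording(p$recording))
  }
})

test_that("invalid source specifications are rejected", {
  expect_error(source_spec(tonic = -1), "nonnegative")
  bad <- source_spec()
  bad$actions$chew$masseter$freq <- 20
  expect_error(emgica:::validate_source_spec(bad), "0.5, 10")
  bad2 <- source_spec()
  bad2$actions$chew$masseter$amp <- -2
  expect_error(emgica:::validate_source_spec(bad2), ">= 0")
  bad3 <- source_spec()
  bad3$actions$chew$masseter$depth <- 1.5
  expect_error(emgica:::validate_source_spec(bad3), "depth")
})
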