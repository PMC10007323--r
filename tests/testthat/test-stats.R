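test_that("one-sample t matches the closed form and flags degeneracy", {
  r <- one_sample_t(c(-1, 1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$d, 0)

  r2 <- one_sample_t(c(1, 2, 3))
  expect_equal(r2$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)  # ~3.4641
  expect_equal(r2$df, 2)
  expect_equal(r2$d, 2)

  expect_error(one_sample_t(c(2, 2, 2)), "variance")
  expect_error(one_sample_t(3), "at least 2")
})

test_that("paired t reduces to the one-sample t on differences", {
  x <- c(3, 5, 9); y <- c(2, 3, 6)
  expect_equal(paired_t(x, y), one_sample_t(c(1, 2, 3)))

  r <- paired_t(c(2, 5), c(1, 2))   # diffs 1, 3
  expect_equal(r$t, 2)
  expect_equal(r$df, 1)
  expect_equal(r$d, sqrt(2), tolerance = 1e-12)

  expect_error(paired_t(c(1, 2), c(1, 2)), "variance")
  expect_error(paired_t(1:3, 1:2), "equal length")
})

test_that("t statistics match the reference implementation to 1e-10", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    x <- rnorm(n, mean = runif(1, -1, 1))
    ref <- t.test(x)
    mine <- one_sample_t(x)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    y <- rnorm(n)
    refp <- t.test(x, y, paired = TRUE)
    minep <- paired_t(x, y)
    expect_equal(minep$t, unname(refp$statistic), tolerance = 1e-10)
    expect_equal(minep$p, refp$p.value, tolerance = 1e-10)
  }
})

test_that("Cohen's d follows the d = t / sqrt(n) convention", {
  set.seed(7)
  x <- rnorm(29, 0.5)
  r <- one_sample_t(x)
  expect_equal(r$d, r$t / sqrt(29), tolerance = 1e-12)
})

# independent oracle: enumerate all 2^n sign assignments
wilcoxon_enumerate <- function(d) {
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  n <- length(d)
  Ws <- vapply(0:(2^n - 1), function(mask) {
    pos <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sum(r[pos])
  }, numeric(1))
  p_le <- mean(Ws <= W_obs)
  p_ge <- mean(Ws >= W_obs)
  min(1, 2 * min(p_le, p_ge))
}

test_that("Wilcoxon exact p comes from full sign enumeration", {
  # all-positive n = 3 -> one-sided 1/8, two-tailed 0.25
  r <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r$p, 0.25)
  expect_equal(r$W, 6)
  expect_equal(r$method, "exact")

  # perfectly symmetric pair
  expect_equal(wilcoxon_signed_rank(c(-1, 1))$p, 1)

  # matches the brute-force enumeration oracle, ties included
  set.seed(11)
  for (i in 1:15) {
    n <- sample(4:9, 1)
    d <- round(rnorm(n, 0.3), if (i %% 2) 3 else 0)
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxon_signed_rank(d)$p, wilcoxon_enumerate(d),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon agrees with the reference implementation (no ties)", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    x <- rnorm(n, 0.4)
    ref <- wilcox.test(x, exact = TRUE)
    mine <- wilcoxon_signed_rank(x)
    expect_equal(mine$W, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact and approximate Wilcoxon p agree at the n = 25 boundary", {
  set.seed(13)
  for (i in 1:8) {
    x <- rnorm(25, 0.2)
    p_exact <- wilcoxon_signed_rank(x, exact_limit = 25)$p
    p_approx <- wilcoxon_signed_rank(x, exact_limit = 0)$p
    expect_lt(abs(p_approx - p_exact), 0.02)
  }
})

test_that("Wilcoxon drops zeros and reports them; all-zero errors", {
  r <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3))
  expect_equal(r$n_zero, 2)
  expect_equal(r$n, 3)
  expect_equal(r$p, 0.25)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
})

# step-down definition applied literally, for cross-checking
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

test_that("Holm adjustment equals the step-down oracle on all permutations", {
  expect_equal(holm_adjust(c(0.001, 0.02, 0.04)), c(0.003, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))

  set.seed(14)
  for (m in 1:6) {
    p <- round(runif(m), 3)
    for (perm in emgica:::all_perms(m)) {
      pp <- p[unlist(perm)]
      expect_equal(holm_adjust(pp), holm_oracle(pp), tolerance = 1e-12)
      expect_equal(holm_adjust(pp), p.adjust(pp, "holm"), tolerance = 1e-12)
    }
  }
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("required sample size comes from exact noncentral-t power", {
  expect_equal(required_sample_size(d = 0.8), 15)
  # cross-check against the stats package's power solver
  ref <- ceiling(power.t.test(delta = 0.5, sd = 1, sig.level = 0.05,
                              power = 0.8, type = "one.sample")$n)
  expect_equal(required_sample_size(d = 0.5), ref)  # 34
  expect_equal(required_sample_size(d = 0.5), 34)
  # monotone nonincreasing in effect size
  expect_lte(required_sample_size(d = 1.2), required_sample_size(d = 0.8))
  expect_error(required_sample_size(d = 0), "unreachable")
})

test_that("report tables cover the muscle x condition grid with Holm families", {
  co <- simulate_cohort(n_participants = 5, master_seed = 6,
                        envelope_domain = TRUE)
  summaries <- do.call(rbind, lapply(seq_along(co), function(i) {
    s <- summarize_conditions(co[[i]]$epochs)
    s$participant <- sprintf("P%02d", i)
    s
  }))
  rep1 <- build_report(summaries)
  expect_equal(nrow(rep1$table1), 32)
  expect_null(rep1$table2)
  expect_true(all(rep1$table1$p_holm >= rep1$table1$p, na.rm = TRUE))
  expect_true(all(rep1$table1$df == 4))
  # Holm is applied within each muscle's 8 conditions
  for (mus in muscle_names()) {
    sub <- rep1$table1[rep1$table1$muscle == mus, ]
    expect_equal(holm_adjust(sub$p), sub$p_holm, tolerance = 1e-12)
  }
})

test_that("identical original and reconstructed amplitudes degenerate cleanly", {
  co <- simulate_cohort(n_participants = 3, master_seed = 9,
                        envelope_domain = TRUE)
  summaries <- do.call(rbind, lapply(seq_along(co), function(i) {
    ep <- co[[i]]$epochs
    s <- summarize_conditions(ep, emg_epochs(ep$participant_id, ep$data,
                                             ep$conditions,
                                             version = "reconstructed"))
    s$participant <- sprintf("P%02d", i)
    s
  }))
  rep2 <- build_report(summaries)
  expect_true(all(rep2$table2$degenerate))
  expect_true(all(is.na(rep2$table2$t)))
  expect_true(!any(rep2$table2$significant))
})
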