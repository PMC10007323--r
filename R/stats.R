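# Statistical battery: one-sample / paired t-tests with Cohen's d,
# Wilcoxon signed-rank (exact by rank-sum enumeration for small n),
# Holm step-down correction, and noncentral-t power analysis.

#' One-sample t-test with Cohen's d
#'
#' `t = (mean(x) - mu0) / (sd(x) / sqrt(n))`, two-tailed p from the
#' Student distribution with `n - 1` degrees of freedom, and
#' `d = (mean(x) - mu0) / sd(x)` (the one-sample Cohen's d convention,
#' under which `d = t / sqrt(n)`).
#'
#' @param x Numeric vector of per-participant values, `n >= 2`, with
#'   nonzero variance.
#' @param mu0 Null value (default 0).
#' @return List with `t`, `df`, `p`, `d`, `n`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  n <- length(x)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  s <- sd(x)
  if (s == 0) stop("zero variance: t statistic undefined", call. = FALSE)
  t_stat <- (mean(x) - mu0) / (s / sqrt(n))
  list(t = t_stat, df = n - 1, p = 2 * pt(-abs(t_stat), n - 1),
       d = (mean(x) - mu0) / s, n = n)
}

#' Paired t-test with Cohen's d
#'
#' One-sample t-test applied to the elementwise differences `x - y`;
#' `d = mean(x - y) / sd(x - y)`.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return List with `t`, `df`, `p`, `d`, `n`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  one_sample_t(x - y, mu0 = 0)
}

# Exact null distribution of the positive-rank sum W by convolution over
# doubled (hence integer, even with midrank ties) ranks.
signed_rank_distribution <- function(ranks2) {
  probs <- numeric(sum(ranks2) + 1)  # index i -> P(W2 = i - 1)
  probs[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), probs[seq_len(length(probs) - r)])
    probs <- 0.5 * (probs + shifted)
  }
  probs
}

#' Wilcoxon signed-rank test
#'
#' One-sample (against `mu0`) or paired test on signed midranks of the
#' absolute differences. Exact zeros are dropped (their count is
#' reported). For `n <= exact_limit` remaining differences the two-tailed
#' p-value is exact, from the full enumeration of sign assignments
#' (computed by convolution over the rank sums, valid under midrank
#' ties); for larger n a normal approximation with continuity and
#' tie-variance corrections is used.
#'
#' @param x Numeric vector.
#' @param y Optional paired vector (test on `x - y`).
#' @param mu0 Null location for the one-sample form (default 0).
#' @param exact_limit Largest n for the exact distribution (default 25).
#' @return List with `W` (positive-rank sum), `p` (two-tailed), `n`
#'   (nonzero differences used), `n_zero` (dropped zeros) and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu0 = 0, exact_limit = 25) {
  d <- if (is.null(y)) x - mu0 else x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    probs <- signed_rank_distribution(round(2 * r))
    w2 <- round(2 * W)
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(W = W, p = p, n = n, n_zero = n_zero, method = method)
}

#' Holm step-down multiple-testing adjustment
#'
#' Sorts the m p-values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotonicity by running maxima and caps at 1;
#' adjusted values are returned in the original order.
#'
#' @param p Numeric vector of probabilities in `[0, 1]` (NA allowed and
#'   propagated; NAs do not count toward m).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  o <- order(p[ok])
  adj <- cummax(pmin(1, (m - seq_len(m) + 1) * p[ok][o]))
  out[ok][o] <- adj
  out
}

#' Required sample size from exact noncentral-t power
#'
#' Smallest `n >= 2` at which a two-tailed one-sample/paired t-test with
#' effect size `d` reaches the target power, computed from the noncentral
#' t distribution with noncentrality `d * sqrt(n)` and `n - 1` degrees of
#' freedom.
#'
#' @param d Effect size (Cohen's d), > 0.
#' @param alpha Two-tailed significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @return Integer sample size.
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.80) {
  if (!(d > 0)) stop("effect size d must be > 0 (power unreachable)",
                     call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  power_at <- function(n) {
    tc <- qt(1 - alpha / 2, n - 1)
    ncp <- d * sqrt(n)
    1 - pt(tc, n - 1, ncp = ncp) + pt(-tc, n - 1, ncp = ncp)
  }
  n <- 2
  while (power_at(n) < power) {
    n <- n + 1
    if (n > 1e6) stop("required sample size exceeds 1e6", call. = FALSE)
  }
  n
}

# One table row: t-test + Wilcoxon for a muscle x condition cell.
stat_cell <- function(muscle, condition, x, y = NULL) {
  row <- data.frame(muscle = muscle, condition = condition,
                    t = NA_real_, df = NA_integer_, p = NA_real_,
                    d = NA_real_, W = NA_real_, p_wilcoxon = NA_real_,
                    n = length(x), degenerate = FALSE,
                    stringsAsFactors = FALSE)
  res <- tryCatch(if (is.null(y)) one_sample_t(x) else paired_t(x, y),
                  error = function(e) NULL)
  wres <- tryCatch(wilcoxon_signed_rank(x, y),
                   error = function(e) NULL)
  if (is.null(res) || is.null(wres)) {
    row$degenerate <- TRUE
    return(row)
  }
  row$t <- res$t
  row$df <- res$df
  row$p <- res$p
  row$d <- res$d
  row$W <- wres$W
  row$p_wilcoxon <- wres$p
  row
}

#' Build the two study report tables
#'
#' From a cohort's stacked condition summaries (see
#' [summarize_conditions()]), computes:
#'
#' * `table1` - per muscle x condition, one-sample t-tests (and Wilcoxon
#'   signed-rank tests) of the original baseline-corrected amplitudes
#'   against zero: does the action elicit (possibly crosstalk) activity?
#' * `table2` - paired t-tests (and Wilcoxon) comparing original against
#'   reconstructed amplitudes: did the reconstruction change the signal?
#'
#' Holm correction is applied within each muscle across its 8 conditions
#' (separately per table and per test family); `significant` flags
#' Holm-corrected `p < 0.05` for the t-tests, `significant_wilcoxon`
#' likewise for the Wilcoxon tests. Cells whose test is undefined (zero
#' variance) are flagged `degenerate`.
#'
#' @param summaries Data frame binding per-participant outputs of
#'   [summarize_conditions()] across the cohort.
#' @param alpha Significance level on the corrected p-values (default
#'   0.05).
#' @return List with data frames `table1` and `table2` (the latter `NULL`
#'   when no reconstructed amplitudes are present), 32 rows each.
#' @export
build_report <- function(summaries, alpha = 0.05) {
  need <- c("participant", "condition", "channel", "version",
            "mean_amplitude")
  if (!all(need %in% names(summaries))) {
    stop("summaries must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  participants <- sort(unique(summaries$participant))
  if (length(participants) < 2) stop("need >= 2 participants", call. = FALSE)
  muscles <- muscle_names()
  conds <- condition_labels()

  fetch <- function(version, muscle, condition) {
    sel <- summaries$version == version & summaries$channel == muscle &
      summaries$condition == condition
    v <- summaries$mean_amplitude[sel][match(participants,
                                             summaries$participant[sel])]
    if (any(is.na(v))) {
      stop("missing cell: ", muscle, " x ", condition, " (", version, ")",
           call. = FALSE)
    }
    v
  }

  finalize <- function(tab) {
    tab$p_holm <- NA_real_
    tab$p_wilcoxon_holm <- NA_real_
    for (mu in muscles) {
      i <- which(tab$muscle == mu)
      tab$p_holm[i] <- holm_adjust(tab$p[i])
      tab$p_wilcoxon_holm[i] <- holm_adjust(tab$p_wilcoxon[i])
    }
    tab$significant <- !is.na(tab$p_holm) & tab$p_holm < alpha
    tab$significant_wilcoxon <- !is.na(tab$p_wilcoxon_holm) &
      tab$p_wilcoxon_holm < alpha
    cols <- c("muscle", "condition", "t", "df", "p", "p_holm", "d",
              "W", "p_wilcoxon", "p_wilcoxon_holm", "n",
              "significant", "significant_wilcoxon", "degenerate")
    tab[cols]
  }

  grid <- expand.grid(muscle = muscles, condition = conds,
                      stringsAsFactors = FALSE)
  table1 <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    stat_cell(grid$muscle[i], grid$condition[i],
              fetch("original", grid$muscle[i], grid$condition[i]))
  }))
  table1 <- finalize(table1)

  table2 <- NULL
  if (any(summaries$version == "reconstructed")) {
    table2 <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      stat_cell(grid$muscle[i], grid$condition[i],
                fetch("original", grid$muscle[i], grid$condition[i]),
                fetch("reconstructed", grid$muscle[i], grid$condition[i]))
    }))
    table2 <- finalize(table2)
  }
  list(table1 = table1, table2 = table2)
}
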