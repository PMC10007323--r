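# Infomax independent component analysis for envelope matrices.
#
# Plain logistic infomax fitted by stochastic natural-gradient ascent on
# the joint entropy of logistic-transformed outputs, equivalent to
# maximum-likelihood ICA with a super-Gaussian (logistic) source prior.
# Centered rectified envelopes are strongly super-Gaussian, so the plain
# (non-extended) score suffices.

#' Center and sphere a channels x timepoints matrix
#'
#' Removes channel means and applies symmetric (ZCA) whitening so the
#' output has identity covariance, the standard preconditioning for
#' infomax.
#'
#' @param X Numeric matrix, channels x timepoints, full row rank, with
#'   more timepoints than channels.
#' @return List with `X` (sphered data), `sphering` (channels x channels
#'   whitening matrix) and `means` (channel means).
#' @export
center_and_sphere <- function(X) {
  stopifnot(is.matrix(X), ncol(X) > nrow(X))
  means <- rowMeans(X)
  Xc <- X - means
  C <- tcrossprod(Xc) / (ncol(X) - 1)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) <= max(e$values) * 1e-12) {
    stop("degenerate input: channels are rank-deficient ",
         "(duplicated or constant channel?)", call. = FALSE)
  }
  sph <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  list(X = sph %*% Xc, sphering = sph, means = means)
}

#' Fit infomax ICA
#'
#' Estimates the unmixing matrix by stochastic natural-gradient ascent on
#' the logistic-infomax objective:
#' `W <- W + lr * (I + (1 - 2 * g(WX)) %*% t(WX) / block) %*% W`
#' with `g` the logistic function, over shuffled data blocks. The learning
#' rate is halved whenever consecutive full-pass weight updates point in
#' opposing directions (oscillation); convergence is declared when the
#' maximum absolute weight change over a pass falls below `tol`.
#'
#' Components are returned in a fixed sign convention: each component's
#' loading on the channel where it holds the largest variance share is
#' positive, making reconstructions comparable across runs and seeds.
#'
#' @param X Channels x timepoints matrix (raw, centered or sphered; the
#'   function sphers internally via [center_and_sphere()]).
#' @param seed RNG seed (required; controls data shuffling).
#' @param lr_init Initial learning rate (default `1e-3 / log(channels)`).
#' @param max_iter Maximum number of passes over the data (default 512).
#' @param tol Convergence tolerance on the per-pass weight change
#'   (default 1e-6).
#' @param block Block size for the stochastic updates (default 128).
#' @return An object of class `emg_ica` with elements `sphering`, `means`,
#'   `W` (unmixing in sphered space), `unmixing` (`W %*% sphering`),
#'   `A_hat` (mixing, channels x components), `S` (component activations,
#'   components x timepoints), `V` (variance shares, channels x
#'   components), `convergence` (iterations, final weight change,
#'   converged flag), `gaussian_warning` (all components near-Gaussian:
#'   rotation not identifiable) and `seed`.
#' @export
fit_infomax <- function(X, seed, lr_init = NULL, max_iter = 512,
                        tol = 1e-6, block = 128) {
  cs <- center_and_sphere(X)
  n_ch <- nrow(X)
  n_t <- ncol(X)
  if (is.null(lr_init)) lr_init <- 1e-3 / log(n_ch)
  Xs <- cs$X
  with_seed(seed, {
    W <- diag(n_ch)
    lr <- lr_init
    I_n <- diag(n_ch)
    prev_dW <- NULL
    delta <- Inf
    best_delta <- Inf
    stall <- 0
    iter <- 0
    while (iter < max_iter && delta >= tol) {
      iter <- iter + 1
      W_old <- W
      perm <- sample.int(n_t)
      starts <- seq(1, n_t, by = block)
      for (s in starts) {
        idx <- perm[s:min(s + block - 1, n_t)]
        U <- W %*% Xs[, idx, drop = FALSE]
        Y <- 1 / (1 + exp(-U))
        grad <- I_n + ((1 - 2 * Y) %*% t(U)) / length(idx)
        W <- W + lr * grad %*% W
        if (any(!is.finite(W)) || max(abs(W)) > 1e8) {
          stop("infomax diverged (weight norm exploded); ",
               "reduce the learning rate", call. = FALSE)
        }
      }
      dW <- W - W_old
      delta <- max(abs(dW))
      # anneal: halve the rate when successive updates reverse direction
      # (oscillation around the optimum) or when the pass-level change has
      # stopped shrinking (stochastic noise floor reached at this rate)
      if (!is.null(prev_dW) && sum(dW * prev_dW) < 0) {
        lr <- lr / 2
        stall <- 0
      } else if (delta >= 0.95 * best_delta) {
        stall <- stall + 1
        if (stall >= 10) {
          lr <- lr / 2
          stall <- 0
        }
      } else {
        stall <- 0
      }
      best_delta <- min(best_delta, delta)
      prev_dW <- dW
    }
    converged <- delta < tol
    if (!converged) {
      warning("infomax did not converge in ", max_iter,
              " passes (final weight change ", signif(delta, 3), ")",
              call. = FALSE)
    }

    unmixing <- W %*% cs$sphering
    A_hat <- solve(unmixing)
    S <- unmixing %*% (X - cs$means)
    V <- variance_shares(A_hat, S)

    # sign convention: positive loading on each component's dominant channel
    for (k in seq_len(n_ch)) {
      dom <- which.max(V[, k])
      if (A_hat[dom, k] < 0) {
        A_hat[, k] <- -A_hat[, k]
        S[k, ] <- -S[k, ]
        unmixing[k, ] <- -unmixing[k, ]
        W[k, ] <- -W[k, ]
      }
    }

    # near-Gaussian components: ICA rotation is not identifiable
    exkurt <- apply(S, 1, function(s) {
      s <- s - mean(s)
      mean(s^4) / mean(s^2)^2 - 3
    })
    structure(
      list(sphering = cs$sphering, means = cs$means, W = W,
           unmixing = unmixing, A_hat = A_hat, S = S, V = V,
           convergence = list(iterations = iter, final_delta = delta,
                              converged = converged),
           gaussian_warning = all(abs(exkurt) < 0.2),
           seed = seed),
      class = "emg_ica")
  })
}

#' @export
print.emg_ica <- function(x, ...) {
  cat("<emg_ica>", nrow(x$S), "components,", ncol(x$S), "timepoints\n")
  cat("  converged:", x$convergence$converged, "after",
      x$convergence$iterations, "passes (delta",
      signif(x$convergence$final_delta, 3), "), seed", x$seed, "\n")
  if (x$gaussian_warning) {
    cat("  warning: all components near-Gaussian; rotation unidentifiable\n")
  }
  invisible(x)
}

#' Component-to-channel variance shares
#'
#' `V[c, k]` is the fraction of channel `c`'s component-attributed
#' variance contributed by component `k`'s back-projection:
#' `var(A_hat[c, k] * S[k, ]) / sum_j var(A_hat[c, j] * S[j, ])`.
#' Each row sums to 1. This is the quantity behind "the component with the
#' highest variance with respect to" a channel.
#'
#' @param A_hat Mixing matrix (channels x components) or an `emg_ica`
#'   object (in which case `S` is taken from it).
#' @param S Component activations (components x timepoints).
#' @return Channels x components matrix of nonnegative row-stochastic
#'   shares.
#' @export
variance_shares <- function(A_hat, S) {
  if (inherits(A_hat, "emg_ica")) {
    S <- A_hat$S
    A_hat <- A_hat$A_hat
  }
  comp_var <- apply(S, 1, var)
  contrib <- sweep(A_hat^2, 2, comp_var, `*`)
  tot <- rowSums(contrib)
  if (any(tot <= 0)) {
    stop("channel(s) with zero back-projected variance: ",
         paste(which(tot <= 0), collapse = ", "), call. = FALSE)
  }
  contrib / tot
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

#' Match estimated components to ground-truth sources
#'
#' Finds the one-to-one assignment of components to sources maximizing the
#' total absolute correlation (exhaustive over permutations; component
#' counts here are small).
#'
#' @param S Component activations (components x timepoints) or an
#'   `emg_ica` object.
#' @param truth Source matrix (sources x timepoints) or an `emg_truth`
#'   whose concatenated envelopes match `S`'s timepoints.
#' @return List with `assignment` (source index for each component) and
#'   `correlations` (per-component absolute correlation with its assigned
#'   source).
#' @export
match_components <- function(S, truth) {
  if (inherits(S, "emg_ica")) S <- S$S
  if (inherits(truth, "emg_truth")) truth <- truth$envelopes
  if (ncol(S) != ncol(truth) || nrow(S) != nrow(truth)) {
    stop("dimension mismatch between components (", nrow(S), "x", ncol(S),
         ") and sources (", nrow(truth), "x", ncol(truth), ")",
         call. = FALSE)
  }
  n <- nrow(S)
  cmat <- abs(cor(t(S), t(truth)))  # comps x sources
  best <- NULL
  best_sum <- -Inf
  for (p in all_perms(n)) {
    s <- sum(cmat[cbind(seq_len(n), p)])
    if (s > best_sum) {
      best_sum <- s
      best <- p
    }
  }
  list(assignment = unlist(best),
       correlations = cmat[cbind(seq_len(n), unlist(best))])
}
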