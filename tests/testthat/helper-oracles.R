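# Independent oracles used across the test files. These deliberately avoid
# the package's own filtering/smoothing code paths.

# Textbook per-dimension Kalman filter: one-step predictions of the next
# observation plus filtered means/variances.
textbook_kf <- function(y, q, r, m0, c, lambda = 1) {
  n <- length(y)
  pred <- fmean <- fvar <- numeric(n)
  m <- m0; s <- c
  for (t in seq_len(n)) {
    if (t > 1) {
      m <- lambda * m
      s <- lambda^2 * s + q
    }
    pred[t] <- m
    g <- s / (s + r)
    m <- m + g * (y[t] - m)
    s <- (1 - g) * s
    fmean[t] <- m
    fvar[t] <- s
  }
  list(pred = pred, fmean = fmean, fvar = fvar)
}

# Exact Gaussian conditioning for one mode's chain (1-D observations):
# states x_{t_j} have cov c + q * (min(t_i, t_j) - t_1) (lambda = 1),
# observations add r on the diagonal. Returns smoothed (all observations)
# and filtered (prefix) conditional means.
joint_gauss_chain <- function(chain, y, q, r, c, m0) {
  n <- length(chain)
  S <- outer(chain, chain, function(a, b) c + q * (pmin(a, b) - chain[1]))
  O <- S + diag(r, n)
  smoothed <- as.numeric(S %*% solve(O, y - m0) + m0)
  filtered <- vapply(seq_len(n), function(j) {
    as.numeric(S[j, 1:j, drop = FALSE] %*%
                 solve(O[1:j, 1:j, drop = FALSE], y[1:j] - m0) + m0)
  }, numeric(1))
  list(smoothed = smoothed, filtered = filtered)
}

# Exhaustive enumeration of CRP partition probabilities (beta = 0) in
# canonical (first-appearance) labelling. Returns a named probability
# vector keyed by the label string, e.g. "1 1 2".
crp_partition_probs <- function(n, alpha) {
  out <- list()
  walk <- function(z, counts, p) {
    t <- length(z) + 1L
    if (t > n) {
      key <- paste(z, collapse = " ")
      out[[key]] <<- (if (is.null(out[[key]])) 0 else out[[key]]) + p
      return(invisible())
    }
    K <- length(counts)
    tot <- sum(counts) + alpha
    if (K > 0) {
      for (k in seq_len(K))
        walk(c(z, k), {cc <- counts; cc[k] <- cc[k] + 1; cc},
             p * counts[k] / tot)
    }
    pn <- if (K == 0) 1 else alpha / tot
    walk(c(z, K + 1L), c(counts, 1), p * pn)
  }
  walk(integer(0), numeric(0), 1)
  unlist(out)
}

# Standard synthetic-agent hyperparameters used as ground truth in fitting
# and behavioural tests (see the methods vignette for the derivation).
truth_hyper <- function() {
  dpkf_hyper(alpha = 0.3, beta = 6, q = c(4, 4), r = c(12, 12),
             v = c(5, 5), decay = 1, m0 = c(50, 50),
             prior_var = c(1000, 1000))
}

null_hyper <- function() {
  dpkf_hyper(alpha = 0, beta = 0, q = c(4, 4), r = c(12, 12),
             v = c(5, 5), decay = 1, m0 = c(50, 50),
             prior_var = c(1000, 1000))
}
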