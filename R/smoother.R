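#' Within-mode Kalman (RTS) smoothing
#'
#' Refines the state estimates of one inferred mode's chain of trials using
#' all of that mode's observations — later observations propagate backward
#' in time, but never across mode boundaries. The mode's observation
#' subsequence is re-filtered with sensory variance `r` + `extra_r` and
#' between-observation diffusion \eqn{\Delta q} (where \eqn{\Delta} is the
#' gap in trials between consecutive chain members), holding the MAP
#' partition fixed; the Rauch-Tung-Striebel backward recursion
#' \deqn{\hat{x}_{t|T} = \hat{x}_{t|t} + J_t(\hat{x}_{succ|T} -
#'   \lambda^\Delta \hat{x}_{t|t}), \quad
#'   J_t = \lambda^\Delta \sigma^2_{t|t} / (\lambda^{2\Delta}
#'   \sigma^2_{t|t} + \Delta q)}
#' then runs from the chain's last trial backward.
#'
#' @param trace A `"dpkf_trace"` from [run_filter()].
#' @param observations The observation matrix the trace was computed from.
#' @param mode Mode label whose chain to smooth.
#' @param hyper Hyperparameters; default those stored in the trace.
#' @param extra_r Nonnegative variance offset added to the sensory noise
#'   during retrieval (0 = plain smoothing).
#' @return A list with `chain` (trial indices of the mode's observations),
#'   `smoothed_mean`, `smoothed_var`, `filtered_mean`, `filtered_var`
#'   (each `length(chain) x n_dims`).
#' @examples
#' h <- dpkf_hyper(alpha = 0, q = 0, r = 4, m0 = 0, prior_var = 1000)
#' y <- c(10, 12, 11, 13)
#' tr <- run_filter(y, h)
#' smooth_mode_chain(tr, y, 1)$smoothed_mean  # all equal: conjugate posterior
#' @export
smooth_mode_chain <- function(trace, observations, mode,
                              hyper = trace$hyper, extra_r = 0) {
  stopifnot_hyper(hyper)
  if (is.vector(observations)) observations <- matrix(observations, ncol = 1L)
  observations <- as.matrix(observations)
  if (extra_r < 0) stop("'extra_r' must be >= 0", call. = FALSE)
  if (!(mode %in% trace$z))
    stop("unknown mode: ", mode, call. = FALSE)
  chain <- which(trace$z == mode)
  n <- length(chain)
  D <- hyper$n_dims
  r_eff <- hyper$r + extra_r
  lam <- hyper$decay

  fm <- fv <- matrix(NA_real_, n, D)   # filtered
  # forward pass along the chain, prior (m0, c) before the first observation
  m <- hyper$m0; s <- hyper$prior_var
  for (j in seq_len(n)) {
    if (j > 1L) {
      delta <- chain[j] - chain[j - 1L]
      ld <- lam^delta
      m <- ld * m
      s <- ld^2 * s + delta * hyper$q
    }
    eta <- s / (s + r_eff)
    m <- m + eta * (observations[chain[j], ] - m)
    s <- (1 - eta) * s
    fm[j, ] <- m
    fv[j, ] <- s
  }
  sm <- fm; sv <- fv
  if (n > 1L) {
    for (j in (n - 1L):1L) {
      delta <- chain[j + 1L] - chain[j]
      ld <- lam^delta
      pv <- ld^2 * fv[j, ] + delta * hyper$q      # variance propagated forward
      J <- ld * fv[j, ] / pv
      sm[j, ] <- fm[j, ] + J * (sm[j + 1L, ] - ld * fm[j, ])
      sv[j, ] <- fv[j, ] + J^2 * (sv[j + 1L, ] - pv)
    }
  }
  list(chain = chain, smoothed_mean = sm, smoothed_var = sv,
       filtered_mean = fm, filtered_var = fv)
}

#' Reconstruct a probed past stimulus from memory
#'
#' The model's prediction for a participant's reconstruction of the
#' stimulus shown on trial `probe_t`: the probed trial's MAP mode is
#' identified, that mode's chain is smoothed with retrieval noise
#' `extra_r` added to the sensory variance (see [smooth_mode_chain()]), and
#' the smoothed estimate at the probe trial is returned. Because smoothing
#' operates within but not across modes, observations assigned to other
#' modes cannot distort the reconstruction.
#'
#' @param trace A `"dpkf_trace"` from [run_filter()].
#' @param observations The observation matrix the trace was computed from.
#' @param probe_t Probed trial index, `1 <= probe_t <= T`.
#' @param hyper Hyperparameters; default those stored in the trace.
#' @param extra_r Retrieval-noise variance offset; the default 5 models the
#'   extra noise of the reconstruction process on the `[0, 100]` stimulus
#'   scale.
#' @return An object of class `"dpkf_reconstruction"`: a list with
#'   `probe_t`, `estimate` (per-dimension), `var`, `mode`, and `chain`
#'   (ordered trial indices sharing the probed trial's mode).
#' @export
reconstruct <- function(trace, observations, probe_t, hyper = trace$hyper,
                        extra_r = 5) {
  if (probe_t < 1 || probe_t > trace$t)
    stop("'probe_t' out of range", call. = FALSE)
  mode <- trace$z[probe_t]
  sm <- smooth_mode_chain(trace, observations, mode, hyper, extra_r)
  j <- match(probe_t, sm$chain)
  structure(list(probe_t = as.integer(probe_t),
                 estimate = sm$smoothed_mean[j, ],
                 var = sm$smoothed_var[j, ],
                 mode = mode, chain = sm$chain),
            class = "dpkf_reconstruction")
}

#' @export
print.dpkf_reconstruction <- function(x, ...) {
  cat(sprintf("Reconstruction of trial %d (mode %d, chain length %d)\n",
              x$probe_t, x$mode, length(x$chain)))
  cat("  estimate:", paste(signif(x$estimate, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize reconstructions to a delimited table
#'
#' @param recons A list of `"dpkf_reconstruction"` objects (one per block).
#' @param participant Participant identifier (recycled).
#' @param path Optional file; if supplied, a tab-separated table is
#'   written.
#' @return A data frame with columns `participant`, `block`, `probe_t`,
#'   per-dimension estimates, `mode` and `chain_length`.
#' @export
reconstruction_table <- function(recons, participant = 1L, path = NULL) {
  D <- length(recons[[1]]$estimate)
  df <- data.frame(participant = rep(participant, length.out = length(recons)),
                   block = seq_along(recons),
                   probe_t = vapply(recons, `[[`, integer(1), "probe_t"))
  for (d in seq_len(D))
    df[[paste0("estimate_dim", d)]] <-
      vapply(recons, function(x) x$estimate[d], numeric(1))
  df$mode <- vapply(recons, `[[`, integer(1), "mode")
  df$chain_length <- vapply(recons, function(x) length(x$chain), integer(1))
  if (!is.null(path))
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}
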