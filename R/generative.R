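#' Sticky Chinese restaurant process prior
#'
#' Probability of the next trial's mode under the sticky Chinese restaurant
#' process. Existing mode \eqn{k} receives weight \eqn{N_k + \beta [k =
#' z_{t-1}]} (usage count plus a stickiness bonus for the previously active
#' mode) and a brand-new mode receives weight \eqn{\alpha}; weights are
#' normalized to a probability vector. With no existing modes the first draw
#' is a new mode with probability 1 (even when `alpha = 0`).
#'
#' @param counts Nonnegative integer usage counts of the existing modes
#'   (length `K`, possibly 0).
#' @param prev_mode Label (index into `counts`) of the mode active on the
#'   previous trial, or `NULL` on the first trial.
#' @param alpha Concentration parameter, `>= 0`.
#' @param beta Stickiness parameter, `>= 0`.
#' @return Numeric probability vector of length `K + 1`; the last entry is
#'   the probability of a new mode.
#' @examples
#' crp_prior(integer(0), NULL, alpha = 1, beta = 2)  # first draw: c(1)
#' crp_prior(c(3), 1, alpha = 1, beta = 2)           # c(5/6, 1/6)
#' crp_prior(c(2, 1), 2, alpha = 0, beta = 0)        # c(2/3, 1/3, 0)
#' @export
crp_prior <- function(counts, prev_mode = NULL, alpha, beta) {
  if (length(counts) && (!is.numeric(counts) || anyNA(counts) ||
                         any(counts < 0) || any(counts != round(counts))))
    stop("'counts' must be nonnegative integers", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("'alpha' must be a scalar >= 0", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("'beta' must be a scalar >= 0", call. = FALSE)
  K <- length(counts)
  if (K == 0L) return(1)
  if (!is.null(prev_mode)) {
    if (length(prev_mode) != 1L || is.na(prev_mode) || prev_mode < 1 ||
        prev_mode > K)
      stop("'prev_mode' must index an existing mode", call. = FALSE)
  }
  w <- as.numeric(counts)
  if (!is.null(prev_mode)) w[prev_mode] <- w[prev_mode] + beta
  w <- c(w, alpha)
  s <- sum(w)
  if (s <= 0)
    stop("degenerate CRP weights: all zero", call. = FALSE)
  w / s
}

#' Simulate the sticky-CRP switching linear-Gaussian generative model
#'
#' At each time step a mode is drawn from [crp_prior()]; a newly created
#' mode's state is drawn per dimension from the Gaussian base measure
#' \eqn{N(m_0, c)}; the state of every previously created mode (active or
#' not) diffuses as \eqn{x \leftarrow \lambda x + N(0, q)}; and the
#' observation is the active mode's state plus sensory noise \eqn{N(0, r)}.
#' Mode labels are assigned in order of first appearance, so partitions are
#' in canonical form.
#'
#' Uses R's global RNG; call [set.seed()] first for reproducibility.
#'
#' @param hyper A [dpkf_hyper()] object.
#' @param n_trials Sequence length `T >= 1`.
#' @return An object of class `"dpkf_sequence"`: a list with
#'   `observations` (`T x n_dims` matrix), `true_modes` (length-`T` integer
#'   labels, first-appearance order), and `true_states` (list of length `T`;
#'   element `t` is the `K_t x n_dims` matrix of all created modes' states
#'   after diffusion at time `t`).
#' @examples
#' set.seed(1)
#' s <- simulate_sequence(dpkf_hyper(alpha = 1, q = 1, r = 0.5), 10)
#' s$true_modes
#' @export
simulate_sequence <- function(hyper, n_trials) {
  stopifnot_hyper(hyper)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1)
    stop("'n_trials' must be >= 1", call. = FALSE)
  n_trials <- as.integer(n_trials)
  D <- hyper$n_dims
  states <- matrix(numeric(0), nrow = 0, ncol = D)  # K x D
  counts <- integer(0)
  z <- integer(n_trials)
  obs <- matrix(NA_real_, n_trials, D)
  state_hist <- vector("list", n_trials)
  prev <- NULL
  for (t in seq_len(n_trials)) {
    p <- crp_prior(counts, prev, hyper$alpha, hyper$beta)
    k <- sample.int(length(p), 1L, prob = p)
    # diffuse every existing mode, then instantiate the new one if drawn
    if (nrow(states) > 0L) {
      states <- hyper$decay * states +
        matrix(rnorm(length(states), 0, rep(sqrt(hyper$q), each = nrow(states))),
               nrow(states), D)
    }
    if (k > length(counts)) {      # new mode
      states <- rbind(states, rnorm(D, hyper$m0, sqrt(hyper$prior_var)))
      counts <- c(counts, 1L)
      k <- length(counts)
    } else {
      counts[k] <- counts[k] + 1L
    }
    obs[t, ] <- states[k, ] + rnorm(D, 0, sqrt(hyper$r))
    z[t] <- k
    state_hist[[t]] <- states
    prev <- k
  }
  structure(list(observations = obs, true_modes = z,
                 true_states = state_hist, hyper = hyper),
            class = "dpkf_sequence")
}

#' @export
print.dpkf_sequence <- function(x, ...) {
  cat(sprintf("Simulated switching-LDS sequence: %d trials, %d dimension(s), %d mode(s)\n",
              nrow(x$observations), ncol(x$observations),
              length(unique(x$true_modes))))
  invisible(x)
}

#' Serialize a simulated sequence to / from a delimited table
#'
#' Columns: `t`, `mode`, `obs_dim1..obs_dimD`, `state_dim1..state_dimD`
#' (the active mode's state). Tab-separated.
#'
#' @param x A `"dpkf_sequence"` object.
#' @param path File path.
#' @return `read_sequence()` returns a data frame; `write_sequence()`
#'   returns `path` invisibly.
#' @export
write_sequence <- function(x, path) {
  stopifnot(inherits(x, "dpkf_sequence"))
  D <- ncol(x$observations)
  active <- t(vapply(seq_along(x$true_modes), function(t)
    x$true_states[[t]][x$true_modes[t], ], numeric(D)))
  df <- data.frame(t = seq_along(x$true_modes), mode = x$true_modes)
  for (d in seq_len(D)) df[[paste0("obs_dim", d)]] <- x$observations[, d]
  for (d in seq_len(D)) df[[paste0("state_dim", d)]] <- active[, d]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) read.delim(path)

#' Morph protocol sequences
#'
#' One-dimensional morph sequences interpolating between 0 and 1, presented
#' either in increasing order (`"gradual"`) or in a uniformly random
#' permutation (`"mixed"`). `morph_index` gives each position's rank in the
#' gradual ordering, so mixed sequences can be re-sorted to match the
#' gradual one (`values[order(morph_index)]`).
#'
#' @param protocol `"gradual"` or `"mixed"`.
#' @param n_morphs Number of morph levels, `>= 2`.
#' @return A list with `values` (observations in presentation order) and
#'   `morph_index` (integer rank `1..n_morphs` of each presented value).
#' @examples
#' morph_sequence("gradual", 5)$values  # 0, 0.25, 0.5, 0.75, 1
#' @export
morph_sequence <- function(protocol = c("gradual", "mixed"), n_morphs) {
  protocol <- match.arg(protocol)
  if (!is.numeric(n_morphs) || length(n_morphs) != 1L || n_morphs < 2)
    stop("'n_morphs' must be >= 2", call. = FALSE)
  n_morphs <- as.integer(n_morphs)
  levels <- seq(0, 1, length.out = n_morphs)
  idx <- if (protocol == "gradual") seq_len(n_morphs) else sample.int(n_morphs)
  list(values = levels[idx], morph_index = idx, protocol = protocol)
}
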