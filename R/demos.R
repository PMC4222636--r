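#' Jump catch-up demonstration
#'
#' A one-dimensional sensory stimulus drifts upward in small constant
#' steps, jumps by a large amount at the midpoint, then resumes drifting.
#' Observations add Gaussian sensory noise with variance `r`. The DP-KF
#' (`alpha = 1`) and an ordinary KF (`alpha = 0`, same `q` and `r`) are run
#' on the same noisy sequences and their one-step absolute prediction
#' errors compared. The catch-up lag of a run is the number of trials
#' after the jump trial until the absolute prediction error first falls
#' below that run's pre-jump median error. By inferring a new mode on the
#' jump trial the DP-KF typically catches up after a single trial, whereas
#' the KF must smooth the jump away gradually.
#'
#' @param n_runs Number of simulated sequences (default 100).
#' @param n_trials Sequence length (default 30; the jump lands between
#'   trials `n_trials/2` and `n_trials/2 + 1`).
#' @param drift Per-trial drift of the stimulus (default 0.5).
#' @param jump Jump magnitude (default 8).
#' @param hyper Model hyperparameters for the DP-KF (1-dimensional; the KF
#'   uses the same values with `alpha = 0`).
#' @param pred_rule Prediction rule, see [run_filter()].
#' @return A list with `lags` (data frame of per-run DP-KF and KF lags),
#'   `median_lag_dpkf`, `median_lag_kf`, and `example` (observations,
#'   predictions and assignments of the first run, for plotting).
#' @examples
#' set.seed(1)
#' d <- demo_jump_catchup(n_runs = 20)
#' d$median_lag_dpkf  # 1
#' @export
demo_jump_catchup <- function(n_runs = 100, n_trials = 30, drift = 0.5,
                              jump = 8,
                              hyper = dpkf_hyper(alpha = 1, beta = 0,
                                                 q = 0.05, r = 1, m0 = 0,
                                                 prior_var = 1000),
                              pred_rule = "prev") {
  stopifnot_hyper(hyper)
  jump_t <- n_trials %/% 2L + 1L          # first post-jump trial
  signal <- drift * (seq_len(n_trials) - 1) + jump * (seq_len(n_trials) >= jump_t)
  hyper_kf <- dpkf_hyper(alpha = 0, beta = 0, q = hyper$q, r = hyper$r,
                         v = hyper$v, decay = hyper$decay, m0 = hyper$m0,
                         prior_var = hyper$prior_var)
  lag_of <- function(err) {
    pre <- median(abs(err[2:(jump_t - 1L)]))   # trial 1 predicts the prior mean
    post <- abs(err[(jump_t + 1L):n_trials])
    hit <- which(post < pre)
    if (length(hit)) hit[1] else n_trials - jump_t
  }
  lags <- data.frame(dpkf = numeric(n_runs), kf = numeric(n_runs))
  example <- NULL
  for (i in seq_len(n_runs)) {
    y <- signal + rnorm(n_trials, 0, sqrt(hyper$r))
    tr1 <- run_filter(y, hyper, pred_rule)
    tr0 <- run_filter(y, hyper_kf, pred_rule)
    lags$dpkf[i] <- lag_of(tr1$prediction_error[, 1])
    lags$kf[i] <- lag_of(tr0$prediction_error[, 1])
    if (i == 1L)
      example <- list(observations = y, signal = signal,
                      dpkf_predicted = tr1$predicted[, 1],
                      kf_predicted = tr0$predicted[, 1],
                      dpkf_modes = tr1$z, jump_t = jump_t)
  }
  list(lags = lags, median_lag_dpkf = median(lags$dpkf),
       median_lag_kf = median(lags$kf), example = example)
}

#' Gradual versus mixed morph protocol demonstration
#'
#' One-dimensional morphs interpolating between 0 and 1 are presented
#' either in increasing order (gradual protocol) or in scrambled order
#' (mixed protocol), and the DP-KF infers mode assignments. Trials are
#' re-sorted by morph index and the posterior probability of the
#' *reference mode* — the MAP mode of the lowest morph — is averaged over
#' runs. Gradual presentation yields a single dominant mode across all
#' morphs; scrambled presentation splits the morphs into two modes with a
#' transition near the middle of the morph continuum.
#'
#' Runs differ only by the random scrambling of the mixed protocol;
#' observations are the noise-free morph values.
#'
#' @param n_runs Number of runs for averaging (default 100).
#' @param n_morphs Number of morph levels (default 20).
#' @param hyper Hyperparameters of the DP-KF on the `[0, 1]` morph scale.
#' @return A list with, per protocol: `posterior` (run-averaged posterior
#'   of the reference mode by morph index), `dominant_modes` (the
#'   across-run majority of the per-run count of modes that hold majority
#'   posterior for at least one morph index), and for the mixed protocol
#'   `transition` (the first morph fraction at which the averaged
#'   reference-mode posterior drops below 0.5).
#' @examples
#' set.seed(1)
#' d <- demo_morph_protocols(n_runs = 20)
#' c(d$gradual$dominant_modes, d$mixed$dominant_modes)  # 1, 2
#' @export
demo_morph_protocols <- function(n_runs = 100, n_morphs = 20,
                                 hyper = dpkf_hyper(alpha = 1, beta = 0,
                                                    q = 0.0016, r = 0.008,
                                                    m0 = 0.5,
                                                    prior_var = 1000)) {
  stopifnot_hyper(hyper)
  run_one <- function(protocol) {
    sq <- morph_sequence(protocol, n_morphs)
    tr <- run_filter(sq$values, hyper)
    ord <- order(sq$morph_index)       # re-sort trials by morph index
    ref <- tr$z[ord[1]]                # MAP mode of the lowest morph
    # posterior of each final mode at each trial; the new-mode slot's mass
    # belongs to label k+1, the label a new mode would receive
    P <- matrix(0, n_morphs, tr$K + 1L)
    for (t in seq_len(n_morphs)) {
      p <- tr$mode_posterior[[t]]
      P[t, seq_along(p)] <- p
    }
    P <- P[, seq_len(tr$K), drop = FALSE]
    P <- P[ord, , drop = FALSE]        # rows now in morph order
    dominant <- sum(apply(P > 0.5, 2L, any))
    list(ref_post = P[, ref], dominant = dominant)
  }
  res <- lapply(c(gradual = "gradual", mixed = "mixed"), function(pr) {
    runs <- replicate(n_runs, run_one(pr), simplify = FALSE)
    post <- rowMeans(vapply(runs, `[[`, numeric(n_morphs), "ref_post"))
    doms <- vapply(runs, `[[`, numeric(1), "dominant")
    counts <- table(doms)
    list(posterior = post,
         dominant_modes = as.integer(names(counts)[which.max(counts)]),
         dominant_mode_runs = counts)
  })
  below <- which(res$mixed$posterior < 0.5)
  res$mixed$transition <- if (length(below))
    (below[1] - 1) / (n_morphs - 1) else NA_real_
  res$morph_fraction <- seq(0, 1, length.out = n_morphs)
  res
}
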