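#' Mode sufficient statistics
#'
#' A dynamical mode is summarized by its per-dimension posterior mean and
#' variance, its usage count \eqn{N_k} and the trial at which it last
#' received an observation. The variance of a mode that has not been active
#' for \eqn{\Delta} trials grows lazily by \eqn{\Delta q} when it is next
#' evaluated (see [predict_mode()]).
#'
#' @param mean Per-dimension posterior mean (stimulus units).
#' @param var Per-dimension posterior variance (`> 0`).
#' @param count Usage count (`>= 1`).
#' @param last_active Trial index at which the mode last received an
#'   observation.
#' @return A list of class `"dpkf_mode"`.
#' @export
mode_state <- function(mean, var, count, last_active) {
  if (any(var <= 0)) stop("'var' must be > 0 componentwise", call. = FALSE)
  if (count < 1) stop("'count' must be >= 1", call. = FALSE)
  if (length(mean) != length(var))
    stop("'mean' and 'var' must have equal length", call. = FALSE)
  structure(list(mean = as.numeric(mean), var = as.numeric(var),
                 count = as.integer(count),
                 last_active = as.integer(last_active)),
            class = "dpkf_mode")
}

#' One-step-ahead prediction for a mode
#'
#' Propagates a mode's posterior to the current trial. With
#' \eqn{\Delta = now - last\_active}: predicted mean
#' \eqn{\lambda^\Delta \hat{x}} and predicted variance
#' \eqn{\lambda^{2\Delta} \sigma^2 + \Delta q} per dimension — the variance
#' of a mode grows with the time since its last occurrence, making long
#' unused modes more tolerant of prediction errors. For a virtual new mode
#' (`state = NULL`) the prediction is the base measure: mean `m0`,
#' variance `prior_var`.
#'
#' @param state A [mode_state()] object, or `NULL` for the virtual new mode.
#' @param now Current trial index; must exceed `state$last_active`.
#' @param hyper A [dpkf_hyper()] object.
#' @return A list with `mean` and `var` (per-dimension).
#' @examples
#' h <- dpkf_hyper(q = 2, r = 1)
#' predict_mode(mode_state(3, 4, 1, 1), now = 6, hyper = h)  # var 4 + 5*2
#' @export
predict_mode <- function(state, now, hyper) {
  stopifnot_hyper(hyper)
  if (is.null(state))
    return(list(mean = hyper$m0, var = hyper$prior_var))
  delta <- now - state$last_active
  if (delta <= 0)
    stop("'now' must exceed the mode's last active trial", call. = FALSE)
  lam <- hyper$decay^delta
  list(mean = lam * state$mean,
       var = lam^2 * state$var + delta * hyper$q)
}

#' Kalman gain
#'
#' The learning rate of the linear-Gaussian update,
#' \eqn{\eta = \sigma^2_{pred} / (\sigma^2_{pred} + r)} per dimension,
#' always in (0, 1).
#'
#' @param pred_var Per-dimension predicted variance (`> 0`).
#' @param r Per-dimension sensory noise variance (`> 0`).
#' @return Per-dimension gain.
#' @examples
#' kalman_gain(1000, 20)  # 1000/1020
#' @export
kalman_gain <- function(pred_var, r) {
  if (any(pred_var <= 0) || any(r <= 0))
    stop("'pred_var' and 'r' must be > 0", call. = FALSE)
  pred_var / (pred_var + r)
}

#' Assimilate an observation into a mode
#'
#' Error-driven update of a mode's posterior: with predicted mean \eqn{m}
#' and variance \eqn{s} from [predict_mode()] and gain
#' \eqn{\eta = s/(s + r)}, the new mean is \eqn{m + \eta (y - m)} and the
#' new variance \eqn{(1 - \eta) s}. The usage count is incremented and
#' `last_active` set to `now`. Returns a new [mode_state()]; the input is
#' not modified.
#'
#' @param state A [mode_state()] or `NULL` to instantiate a new mode from
#'   the base measure.
#' @param y Observation (per-dimension, finite).
#' @param now Current trial index.
#' @param hyper A [dpkf_hyper()] object.
#' @return An updated [mode_state()].
#' @examples
#' h <- dpkf_hyper(r = 20, m0 = 50, prior_var = 1000)
#' update_mode(NULL, y = 80, now = 1, hyper = h)  # mean ~79.41, var ~19.61
#' @export
update_mode <- function(state, y, now, hyper) {
  stopifnot_hyper(hyper)
  if (anyNA(y) || any(!is.finite(y)))
    stop("'y' must be finite", call. = FALSE)
  if (length(y) != hyper$n_dims)
    stop("'y' must have n_dims entries", call. = FALSE)
  pred <- predict_mode(state, now, hyper)
  eta <- kalman_gain(pred$var, hyper$r)
  mode_state(mean = pred$mean + eta * (y - pred$mean),
             var = (1 - eta) * pred$var,
             count = if (is.null(state)) 1L else state$count + 1L,
             last_active = now)
}

#' Predictive log-likelihood of an observation under a mode
#'
#' Log density of `y` under the mode's one-step predictive distribution:
#' per dimension Gaussian with the [predict_mode()] mean and variance plus
#' sensory noise `r`, summed over dimensions. For the never-instantiated
#' new mode (`state = NULL`) the predictive is \eqn{N(m_0, c + r)}; with a
#' large prior variance `c` this depends only weakly on `y`.
#'
#' @inheritParams update_mode
#' @return Scalar log-likelihood.
#' @export
mode_loglik <- function(state, y, now, hyper) {
  stopifnot_hyper(hyper)
  if (length(y) != hyper$n_dims)
    stop("'y' must have n_dims entries", call. = FALSE)
  pred <- predict_mode(state, now, hyper)
  sum(dnorm(y, pred$mean, sqrt(pred$var + hyper$r), log = TRUE))
}

# Empty filter state for a sequence of observations.
filter_init <- function(hyper, pred_rule = "prev") {
  D <- hyper$n_dims
  list(hyper = hyper, pred_rule = pred_rule, t = 0L,
       modes = list(mean = matrix(numeric(0), 0, D),
                    var = matrix(numeric(0), 0, D),
                    count = integer(0), last = integer(0)),
       z = integer(0),
       observations = matrix(numeric(0), 0, D),
       predicted = matrix(numeric(0), 0, D),
       prediction_error = matrix(numeric(0), 0, D),
       mode_posterior = list())
}

# Behavioural one-step prediction of y_t before observing it.
predict_observation <- function(trace, hyper = trace$hyper) {
  t <- trace$t + 1L
  md <- trace$modes
  K <- length(md$count)
  if (K == 0L) return(hyper$m0)
  prev <- trace$z[trace$t]
  lam <- function(k) hyper$decay^(t - md$last[k])
  switch(trace$pred_rule,
    prev = lam(prev) * md$mean[prev, ],
    mixture = {
      p <- crp_prior(md$count, prev, hyper$alpha, hyper$beta)
      mix <- p[K + 1L] * hyper$m0
      for (k in seq_len(K)) mix <- mix + p[k] * (lam(k) * md$mean[k, ])
      mix
    },
    map_prior = {
      p <- crp_prior(md$count, prev, hyper$alpha, hyper$beta)
      k <- which.max(p + c(rep(1e-15, K), 0))  # existing modes win exact ties
      if (k > K) hyper$m0 else lam(k) * md$mean[k, ]
    },
    stop("unknown prediction rule: ", trace$pred_rule, call. = FALSE))
}

#' Advance the DP-KF by one trial
#'
#' The sequential inference step of the Dirichlet-process Kalman filter
#' under the local (single-partition) approximation:
#' (i) the behavioural prediction of `y` is formed before the observation
#' (see `pred_rule` in [run_filter()]);
#' (ii) the posterior over mode assignments is computed by combining the
#' sticky CRP prior ([crp_prior()]) with each mode's predictive
#' log-likelihood ([mode_loglik()]), normalized in log space;
#' (iii) the trial is hard-assigned to the MAP mode (ties broken toward the
#' lowest label, with existing modes beating the new mode);
#' (iv) only the assigned mode is updated ([update_mode()]); other modes'
#' variance growth is realized lazily through their `last_active` trial.
#'
#' @param trace A filter trace as returned by [run_filter()] (or an
#'   in-progress trace).
#' @param y Observation for the next trial (`n_dims` entries).
#' @param hyper Hyperparameters; defaults to those stored in the trace.
#' @return The updated trace.
#' @export
filter_step <- function(trace, y, hyper = trace$hyper) {
  y <- as.numeric(y)
  if (length(y) != hyper$n_dims)
    stop("dimension mismatch: 'y' must have n_dims entries", call. = FALSE)
  t <- trace$t + 1L
  md <- trace$modes
  K <- length(md$count)

  pred_y <- predict_observation(trace, hyper)

  prior <- crp_prior(md$count, if (t > 1L) trace$z[t - 1L] else NULL,
                     hyper$alpha, hyper$beta)
  loglik <- numeric(K + 1L)
  if (K > 0L) {
    delta <- t - md$last
    lam <- hyper$decay^delta
    pm <- md$mean * lam                  # lam recycles down columns: row k scaled by lam[k]
    pv <- md$var * lam^2 + outer(delta, hyper$q)
    tot <- sweep(pv, 2L, hyper$r, `+`)
    for (k in seq_len(K))
      loglik[k] <- sum(dnorm(y, pm[k, ], sqrt(tot[k, ]), log = TRUE))
  }
  loglik[K + 1L] <- sum(dnorm(y, hyper$m0,
                              sqrt(hyper$prior_var + hyper$r), log = TRUE))
  logpost <- log(prior) + loglik
  post <- exp(logpost - max(logpost[is.finite(logpost)]))
  post[!is.finite(logpost)] <- 0
  post <- post / sum(post)

  # argmax with deterministic tie-breaking: lowest label, existing before new
  zt <- which.max(post + c(rep(1e-15, K), 0))
  if (zt > K) {                       # instantiate a new mode
    st <- update_mode(NULL, y, t, hyper)
    md$mean <- rbind(md$mean, st$mean)
    md$var <- rbind(md$var, st$var)
    md$count <- c(md$count, 1L)
    md$last <- c(md$last, t)
    zt <- K + 1L
  } else {
    st <- update_mode(mode_state(md$mean[zt, ], md$var[zt, ], md$count[zt],
                                 md$last[zt]), y, t, hyper)
    md$mean[zt, ] <- st$mean
    md$var[zt, ] <- st$var
    md$count[zt] <- st$count
    md$last[zt] <- t
  }

  trace$t <- t
  trace$modes <- md
  trace$z <- c(trace$z, zt)
  trace$observations <- rbind(trace$observations, y)
  trace$predicted <- rbind(trace$predicted, pred_y)
  trace$prediction_error <- rbind(trace$prediction_error, y - pred_y)
  trace$mode_posterior[[t]] <- post
  trace
}

#' Run the Dirichlet-process Kalman filter over a sequence
#'
#' Folds [filter_step()] over the rows of `observations`. Inference is
#' fully deterministic given its inputs (no sampling is used anywhere).
#' Setting `alpha = 0` in `hyper` recovers an ordinary per-dimension Kalman
#' filter; additionally setting `q = 0` gives the stationary
#' (running-average) filter.
#'
#' @param observations Numeric `T x n_dims` matrix (a vector is taken as a
#'   1-dimensional sequence).
#' @param hyper A [dpkf_hyper()] object.
#' @param pred_rule How the trial-wise behavioural prediction is formed
#'   before seeing the observation: `"prev"` (default) propagates the
#'   filtered mean of the previously active (MAP) mode — the filtered state
#'   estimate; `"mixture"` is the CRP-prior-weighted mixture mean over all
#'   modes including the new-mode term at `m0`; `"map_prior"` uses the
#'   single mode maximizing the CRP prior. On trial 1 all rules predict
#'   `m0`.
#' @return An object of class `"dpkf_trace"`: a list with per-trial
#'   `predicted`, `prediction_error`, `mode_posterior` (list of probability
#'   vectors over instantiated modes plus the new-mode slot), `z` (MAP
#'   assignments), and final `modes` (means, variances, counts, last-active
#'   trials) and `K`.
#' @examples
#' h <- dpkf_hyper(alpha = 1, q = 0.05, r = 1, prior_var = 1000)
#' y <- c(0.1, 0.3, 0.2, 6.1, 6.3, 6.2)
#' tr <- run_filter(y, h)
#' tr$z   # the jump opens a second mode
#' @export
run_filter <- function(observations, hyper,
                       pred_rule = c("prev", "mixture", "map_prior")) {
  stopifnot_hyper(hyper)
  pred_rule <- match.arg(pred_rule)
  if (is.vector(observations)) observations <- matrix(observations, ncol = 1L)
  observations <- as.matrix(observations)
  if (nrow(observations) < 1L)
    stop("'observations' must contain at least one trial", call. = FALSE)
  if (ncol(observations) != hyper$n_dims)
    stop("'observations' must have n_dims columns", call. = FALSE)
  trace <- filter_init(hyper, pred_rule)
  for (t in seq_len(nrow(observations)))
    trace <- filter_step(trace, observations[t, ], hyper)
  trace$K <- length(trace$modes$count)
  dimnames(trace$predicted) <- NULL
  dimnames(trace$prediction_error) <- NULL
  dimnames(trace$observations) <- NULL
  class(trace) <- "dpkf_trace"
  trace
}

#' @export
print.dpkf_trace <- function(x, ...) {
  cat(sprintf("DP-KF trace: %d trials, %d dimension(s), %d inferred mode(s)\n",
              x$t, ncol(x$observations), x$K))
  cat("mode assignments:", paste(x$z, collapse = " "), "\n")
  invisible(x)
}

#' @describeIn run_filter per-trial table: `t`, predicted means, MAP mode,
#'   and the mode posterior as a JSON-encoded list column.
#' @param x,row.names,optional,... standard [as.data.frame()] arguments.
#' @export
as.data.frame.dpkf_trace <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  D <- ncol(x$observations)
  df <- data.frame(t = seq_len(x$t))
  for (d in seq_len(D)) df[[paste0("predicted_dim", d)]] <- x$predicted[, d]
  df$map_mode <- x$z
  df$posterior <- vapply(x$mode_posterior, function(p)
    as.character(jsonlite::toJSON(unname(p), digits = NA)), character(1))
  df
}

#' @describeIn run_filter JSON summary (K, assignments, final mode states)
#'   written to `path`.
#' @param trace A `"dpkf_trace"` object.
#' @param path Output file.
#' @export
write_trace_summary <- function(trace, path) {
  stopifnot(inherits(trace, "dpkf_trace"))
  md <- trace$modes
  out <- list(K = trace$K, assignments = trace$z,
              modes = lapply(seq_len(trace$K), function(k)
                list(mean = md$mean[k, ], var = md$var[k, ],
                     count = md$count[k], last_active = md$last[k])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
plot.dpkf_trace <- function(x, dim = 1L, ...) {
  t <- seq_len(x$t)
  obs <- x$observations[, dim]
  pred <- x$predicted[, dim]
  plot(t, obs, type = "p", pch = 21, bg = x$z, xlab = "trial",
       ylab = sprintf("dimension %d", dim), ...)
  graphics::lines(t, pred, lty = 2)
  graphics::legend("topleft", legend = c("observation (fill = mode)",
                                         "one-step prediction"),
                   pch = c(21, NA), lty = c(NA, 2), bty = "n")
  invisible(x)
}
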