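#' @export
print.dpkf_fit <- function(x, ...) {
  cat(sprintf("Model fit: %s variant, participant %s\n", x$variant,
              as.character(x$participant_id)))
  cat(sprintf("  %d free parameter(s), %d block(s), train NLL %.3f\n",
              length(x$coefficients), length(x$blocks), x$train_nll))
  cat("  coefficients:\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.dpkf_fit <- function(object, ...) object$coefficients

#' @export
logLik.dpkf_fit <- function(object, ...) {
  structure(-object$train_nll, df = length(object$coefficients),
            nobs = object$n_obs, class = "logLik")
}

#' @export
summary.dpkf_fit <- function(object, ...) {
  out <- list(fit = object,
              restart_spread = diff(range(object$restart_nlls)),
              K_by_block = vapply(seq_along(object$session$blocks),
                                  function(b) {
                blk <- object$session$blocks[[b]]
                run_filter(blk$stimuli, object$hyper, object$pred_rule)$K
              }, integer(1)))
  conds <- vapply(object$session$blocks, `[[`, character(1), "condition")
  out$K_by_condition <- tapply(out$K_by_block, conds, mean)
  class(out) <- "summary.dpkf_fit"
  out
}

#' @export
print.summary.dpkf_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  restart NLL spread: %.4g\n", x$restart_spread))
  cat("  mean inferred modes per condition:\n")
  print(signif(x$K_by_condition, 3))
  invisible(x)
}

#' Model predictions for a session
#'
#' Trial-wise one-step predictions (`type = "prediction"`) or per-block
#' reconstructions of the probed trials (`type = "reconstruction"`) under
#' the fitted hyperparameters, computed by re-running the filter (and,
#' for reconstructions, the within-mode smoother with retrieval noise
#' `extra_r`).
#'
#' @param object A `"dpkf_fit"`.
#' @param newdata A `"dpkf_session"`; defaults to the fitted session.
#' @param type `"prediction"` or `"reconstruction"`.
#' @param extra_r Retrieval-noise offset for reconstructions.
#' @param ... Unused.
#' @return For `"prediction"`, a list of per-block `n_trials x 2`
#'   matrices; for `"reconstruction"`, a `n_blocks x 2` matrix.
#' @export
predict.dpkf_fit <- function(object, newdata = NULL,
                             type = c("prediction", "reconstruction"),
                             extra_r = 5, ...) {
  type <- match.arg(type)
  session <- if (is.null(newdata)) object$session else newdata
  stopifnot(inherits(session, "dpkf_session"))
  if (type == "prediction") {
    lapply(session$blocks, function(blk)
      run_filter(blk$stimuli, object$hyper, object$pred_rule)$predicted)
  } else {
    t(vapply(session$blocks, function(blk) {
      tr <- run_filter(blk$stimuli, object$hyper, object$pred_rule)
      reconstruct(tr, blk$stimuli, blk$probe_t, object$hyper,
                  extra_r)$estimate
    }, numeric(2)))
  }
}

#' @export
residuals.dpkf_fit <- function(object, ...) {
  preds <- predict(object, type = "prediction")
  do.call(rbind, lapply(seq_along(preds), function(b)
    object$responses$predictions[[b]] - preds[[b]]))
}

#' Simulate response sets from a fitted model
#'
#' Draws `nsim` synthetic response sets for the fitted session under the
#' fitted hyperparameters (predictions and reconstructions corrupted by
#' the fitted response noise `v`), via [simulate_responses()].
#'
#' @param object A `"dpkf_fit"`.
#' @param nsim Number of response sets.
#' @param seed Optional seed passed to [set.seed()].
#' @param ... Unused.
#' @return A list of `nsim` `"dpkf_responses"` objects.
#' @export
simulate.dpkf_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim,
            simulate_responses(object$session, object$hyper,
                               object$pred_rule),
            simplify = FALSE)
}

#' @export
plot.dpkf_fit <- function(x, block = 1L, ...) {
  blk <- x$session$blocks[[block]]
  tr <- run_filter(blk$stimuli, x$hyper, x$pred_rule)
  stim <- blk$stimuli
  plot(stim[, 1], stim[, 2], type = "b", pch = 21, bg = tr$z,
       xlab = "angle (standardized units)",
       ylab = "length (standardized units)",
       main = sprintf("participant %s, %s block %d (%s fit)",
                      as.character(x$participant_id), blk$condition, block,
                      x$variant), ...)
  graphics::points(tr$predicted[, 1], tr$predicted[, 2], pch = 4)
  obs_resp <- x$responses$predictions[[block]]
  graphics::points(obs_resp[, 1], obs_resp[, 2], pch = 3, col = "grey40")
  graphics::legend("topleft",
                   legend = c("stimulus (fill = inferred mode)",
                              "model prediction", "response"),
                   pch = c(21, 4, 3), bty = "n")
  invisible(x)
}
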