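#' Negative log-likelihood of prediction-trial responses
#'
#' Runs the filter over each block's observed stimuli (deterministically)
#' and scores the participant's trial-wise predictions under anisotropic
#' Gaussian response noise: \eqn{-\sum \log N(resp; pred, v^d)} over the
#' included prediction trials and dimensions. Reconstruction trials are
#' never included. Stimuli are expected on the rescaled `[0, 100]` scale.
#'
#' @param responses A `"dpkf_responses"` object (see [simulate_responses()]
#'   or [read_session()]).
#' @param session The matching `"dpkf_session"`.
#' @param hyper A [dpkf_hyper()] object (2-dimensional).
#' @param blocks Integer indices of the blocks to include (default all).
#' @param include_trial1 Include the trial-1 prediction, scored against the
#'   prior mean `m0` (default `TRUE`).
#' @param pred_rule Prediction rule, see [run_filter()].
#' @return Scalar negative log-likelihood.
#' @export
response_nll <- function(responses, session, hyper,
                         blocks = seq_along(session$blocks),
                         include_trial1 = TRUE,
                         pred_rule = c("prev", "mixture", "map_prior")) {
  stopifnot(inherits(responses, "dpkf_responses"),
            inherits(session, "dpkf_session"))
  stopifnot_hyper(hyper)
  pred_rule <- match.arg(pred_rule)
  if (length(blocks) == 0L)
    stop("'blocks' must select at least one block", call. = FALSE)
  rule <- match(pred_rule, c("prev", "mixture", "map_prior")) - 1L
  nll <- 0
  for (b in blocks) {
    nll <- nll + cpp_block_nll(
      unname(session$blocks[[b]]$stimuli),
      unname(responses$predictions[[b]]),
      hyper$alpha, hyper$beta, hyper$q, hyper$r, hyper$v,
      hyper$decay, hyper$m0, hyper$prior_var, rule, include_trial1)
  }
  nll
}

#' Fit a model variant to one participant's prediction responses
#'
#' Maximum-likelihood estimation of a model variant's free parameters
#' ([variant_spec()]) by minimizing [response_nll()] with box constraints
#' (`v` at 10, `q` at 30, `r` at 20, `alpha` at 10, `beta` at 20,
#' variances bounded away from 0), using `L-BFGS-B` started from
#' `n_restarts` random interior points (Nelder-Mead fallback if a start
#' fails numerically). The prior mean is fixed at the centre of the
#' stimulus space (50, 50) and the prior variance at 1000. Reconstruction
#' trials are never used for fitting.
#'
#' Stochastic only through the random starting points: seed the RNG with
#' [set.seed()] to make refits identical.
#'
#' @param responses A `"dpkf_responses"` object, or a tidy data frame in
#'   the [session_table()] layout (from which session and responses are
#'   rebuilt).
#' @param session The matching `"dpkf_session"` (ignored when `responses`
#'   is a data frame).
#' @param variant One of [dpkf_variants()].
#' @param n_restarts Number of random starting points (default 3).
#' @param blocks Blocks used for fitting (default all).
#' @param include_trial1,pred_rule Passed to [response_nll()].
#' @param control Passed to [stats::optim()]; the default sets a
#'   convergence tolerance of about 1e-6 on the NLL.
#' @return An object of class `"dpkf_fit"` with components `coefficients`
#'   (named free-parameter estimates), `hyper` (full [dpkf_hyper()]),
#'   `variant`, `train_nll`, `restart_nlls`, `restart_pars`,
#'   `convergence`, `participant_id`, `blocks`, plus the data needed by
#'   the methods ([predict.dpkf_fit()], [logLik.dpkf_fit()], ...).
#' @examples
#' \donttest{
#' set.seed(7)
#' sess <- build_session(1)
#' truth <- dpkf_hyper(alpha = 1, beta = 4, q = c(5, 5), r = c(10, 10),
#'                     v = c(5, 5), m0 = c(50, 50))
#' resp <- simulate_responses(sess, truth)
#' fit <- dpkf_fit(resp, sess, "dpkf")
#' coef(fit)
#' }
#' @export
dpkf_fit <- function(responses, session = NULL,
                     variant = c("dpkf", "kf", "stationary_dpkf",
                                 "stationary_kf"),
                     n_restarts = 3L, blocks = NULL,
                     include_trial1 = TRUE,
                     pred_rule = c("prev", "mixture", "map_prior"),
                     control = list(maxit = 500L, factr = 1e8)) {
  variant <- match.arg(variant)
  pred_rule <- match.arg(pred_rule)
  if (is.data.frame(responses)) {
    parsed <- read_session(responses)
    if (is.null(parsed$responses))
      stop("the data frame contains no responses", call. = FALSE)
    session <- parsed$session
    responses <- parsed$responses
  }
  stopifnot(inherits(responses, "dpkf_responses"),
            inherits(session, "dpkf_session"))
  if (is.null(blocks)) blocks <- seq_along(session$blocks)
  base <- dpkf_hyper(m0 = c(50, 50), prior_var = c(1000, 1000),
                     r = c(1, 1), v = c(1, 1), n_dims = 2L)
  vs <- variant_spec(variant, base$n_dims)
  obj <- function(par) {
    names(par) <- vs$free
    h <- variant_hyper(par, vs, base)
    response_nll(responses, session, h, blocks, include_trial1, pred_rule)
  }
  np <- length(vs$free)
  restarts <- vector("list", n_restarts)
  for (i in seq_len(n_restarts)) {
    start <- vs$lower + runif(np) * (vs$upper - vs$lower)
    fit <- tryCatch(
      optim(start, obj, method = "L-BFGS-B", lower = vs$lower,
            upper = vs$upper, control = control),
      error = function(e) NULL)
    if (is.null(fit)) {
      # Nelder-Mead on a logistic transform of the box as a fallback
      tr <- function(x) vs$lower + (vs$upper - vs$lower) / (1 + exp(-x))
      inv <- function(p) {
        z <- (p - vs$lower) / (vs$upper - vs$lower)
        z <- pmin(pmax(z, 1e-8), 1 - 1e-8)
        log(z / (1 - z))
      }
      fit <- tryCatch(
        optim(inv(start), function(x) obj(tr(x)), method = "Nelder-Mead",
              control = list(maxit = 2000L)),
        error = function(e) NULL)
      if (!is.null(fit)) fit$par <- tr(fit$par)
    }
    restarts[[i]] <- fit
  }
  ok <- !vapply(restarts, is.null, logical(1))
  if (!any(ok))
    stop("model fitting failed: no restart converged (variant ", variant,
         ", participant ", session$participant_id, ")", call. = FALSE)
  restarts <- restarts[ok]
  nlls <- vapply(restarts, `[[`, numeric(1), "value")
  best <- restarts[[which.min(nlls)]]
  # polish the best restart: a derivative-free pass on a logistic transform
  # of the box rides out the kinks that hard MAP reassignment puts in the
  # likelihood surface, then one more bounded quasi-Newton pass
  tr <- function(x) vs$lower + (vs$upper - vs$lower) / (1 + exp(-x))
  inv <- function(p) {
    z <- (p - vs$lower) / (vs$upper - vs$lower)
    z <- pmin(pmax(z, 1e-8), 1 - 1e-8)
    log(z / (1 - z))
  }
  pol <- tryCatch(
    optim(inv(best$par), function(x) obj(tr(x)), method = "Nelder-Mead",
          control = list(maxit = 2000L, reltol = 1e-10)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value)
    best <- list(par = tr(pol$par), value = pol$value,
                 convergence = pol$convergence)
  pol2 <- tryCatch(
    optim(best$par, obj, method = "L-BFGS-B", lower = vs$lower,
          upper = vs$upper, control = control),
    error = function(e) NULL)
  if (!is.null(pol2) && pol2$value < best$value) best <- pol2
  nlls[which.min(nlls)] <- best$value
  par <- setNames(best$par, vs$free)
  hyper <- variant_hyper(par, vs, base)
  n_pred <- sum(vapply(session$blocks[blocks], function(b)
    nrow(b$stimuli), integer(1))) - if (include_trial1) 0L else length(blocks)
  structure(
    list(coefficients = par, hyper = hyper, variant = variant,
         train_nll = min(nlls), restart_nlls = nlls,
         restart_pars = lapply(restarts, `[[`, "par"),
         convergence = best$convergence,
         participant_id = session$participant_id,
         blocks = blocks, include_trial1 = include_trial1,
         pred_rule = pred_rule, n_obs = n_pred * base$n_dims,
         session = session, responses = responses, spec = vs),
    class = "dpkf_fit")
}

#' Cross-validated predictive log-likelihood (even/odd block split)
#'
#' Fits the variant on the odd-numbered blocks and evaluates the
#' prediction-trial log-likelihood on the even-numbered blocks, then vice
#' versa. Reconstruction trials are excluded throughout.
#'
#' @inheritParams dpkf_fit
#' @return A list with `heldout_ll` (summed held-out log-likelihood over
#'   both folds), `train_ll` (summed training log-likelihood, for
#'   overfitting checks), and `folds` (per-fold detail including the
#'   fitted objects).
#' @export
crossval_predictive_ll <- function(responses, session,
                                   variant = c("dpkf", "kf",
                                               "stationary_dpkf",
                                               "stationary_kf"),
                                   n_restarts = 3L, include_trial1 = TRUE,
                                   pred_rule = "prev") {
  variant <- match.arg(variant)
  nb <- length(session$blocks)
  odd <- seq(1L, nb, by = 2L)
  even <- seq(2L, nb, by = 2L)
  folds <- lapply(list(list(train = odd, test = even),
                       list(train = even, test = odd)), function(f) {
    fit <- dpkf_fit(responses, session, variant, n_restarts,
                    blocks = f$train, include_trial1 = include_trial1,
                    pred_rule = pred_rule)
    list(fit = fit, train = f$train, test = f$test,
         train_ll = -fit$train_nll,
         test_ll = -response_nll(responses, session, fit$hyper, f$test,
                                 include_trial1, pred_rule))
  })
  list(heldout_ll = sum(vapply(folds, `[[`, numeric(1), "test_ll")),
       train_ll = sum(vapply(folds, `[[`, numeric(1), "train_ll")),
       folds = folds)
}

#' Predictive log-likelihood of reconstruction responses
#'
#' Scores each block's reconstruction response under a Gaussian centred on
#' the model's reconstruction ([reconstruct()] with retrieval noise
#' `extra_r`) with response variance `v`. The model is fit to prediction
#' trials only, so this is a held-out comparison that needs no complexity
#' penalty.
#'
#' @param responses,session As in [dpkf_fit()].
#' @param hyper Fitted hyperparameters (a [dpkf_hyper()] or a
#'   `"dpkf_fit"`).
#' @param extra_r Retrieval-noise offset (default 5).
#' @param pred_rule Prediction rule used when re-running the filter.
#' @return Scalar log-likelihood summed over blocks.
#' @export
reconstruction_ll <- function(responses, session, hyper, extra_r = 5,
                              pred_rule = "prev") {
  if (inherits(hyper, "dpkf_fit")) hyper <- hyper$hyper
  stopifnot_hyper(hyper)
  ll <- 0
  for (b in seq_along(session$blocks)) {
    blk <- session$blocks[[b]]
    tr <- run_filter(blk$stimuli, hyper, pred_rule)
    rec <- reconstruct(tr, blk$stimuli, blk$probe_t, hyper, extra_r)
    ll <- ll + sum(dnorm(responses$reconstructions[[b]], rec$estimate,
                         sqrt(hyper$v), log = TRUE))
  }
  ll
}

#' Serialize fit results to JSON
#'
#' One record per fit with participant, variant, coefficients, training
#' NLL and restart provenance.
#'
#' @param fits A `"dpkf_fit"` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fits, path) {
  if (inherits(fits, "dpkf_fit")) fits <- list(fits)
  recs <- lapply(fits, function(f) {
    list(participant = f$participant_id, variant = f$variant,
         coefficients = as.list(f$coefficients), train_nll = f$train_nll,
         restart_nlls = f$restart_nlls, convergence = f$convergence)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
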