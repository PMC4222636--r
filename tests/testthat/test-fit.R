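# A small fixed dataset shared by the fitting tests (2 participants).
set.seed(41)
sessions <- lapply(1:2, build_session)
truth <- truth_hyper()
responses <- lapply(sessions, simulate_responses, hyper_true = truth)

test_that("variant specifications encode the nested parameter structure", {
  counts <- vapply(dpkf_variants(), function(v)
    length(variant_spec(v)$free), integer(1))
  expect_identical(unname(counts), c(5L, 7L, 7L, 9L))
  expect_identical(variant_spec("stationary_kf")$fixed$q, 0)
  expect_identical(variant_spec("stationary_kf")$fixed$alpha, 0)
  expect_identical(variant_spec("kf")$fixed$alpha, 0)
  expect_null(variant_spec("kf")$fixed$q)
  expect_identical(variant_spec("stationary_dpkf")$fixed$q, 0)
  expect_null(variant_spec("dpkf")$fixed$alpha)
  vs <- variant_spec("dpkf")
  expect_true(all(vs$lower < vs$upper))
  expect_identical(unname(vs$upper[c("v1", "r1", "q1", "alpha", "beta")]),
                   c(10, 20, 30, 10, 20))
})

test_that("noise-free responses give exactly the Gaussian constant NLL", {
  sess <- sessions[[1]]
  h <- truth
  preds <- lapply(sess$blocks, function(b) run_filter(b$stimuli, h)$predicted)
  exact <- structure(list(predictions = preds,
                          reconstructions = lapply(1:12, function(i) c(0, 0)),
                          generator = "synthetic", hyper_true = h,
                          participant_id = 1L),
                     class = "dpkf_responses")
  nll <- response_nll(exact, sess, h)
  const <- 12 * 18 * sum(0.5 * log(2 * pi * h$v))
  expect_equal(nll, const, tolerance = 1e-10)
  # dropping trial 1 removes exactly one trial's constant per block
  nll0 <- response_nll(exact, sess, h, include_trial1 = FALSE)
  expect_equal(nll0, const * 17 / 18, tolerance = 1e-10)
})

test_that("response NLL is additive over blocks", {
  nll_all <- response_nll(responses[[1]], sessions[[1]], truth)
  nll_sum <- sum(vapply(1:12, function(b)
    response_nll(responses[[1]], sessions[[1]], truth, blocks = b),
    numeric(1)))
  expect_equal(nll_all, nll_sum, tolerance = 1e-10)
  expect_error(response_nll(responses[[1]], sessions[[1]], truth,
                            blocks = integer(0)), "at least one")
})

test_that("shrinking v below the residual variance increases the NLL", {
  h_small <- dpkf_hyper(alpha = truth$alpha, beta = truth$beta, q = truth$q,
                        r = truth$r, v = truth$v / 4, m0 = truth$m0,
                        prior_var = truth$prior_var)
  expect_gt(response_nll(responses[[1]], sessions[[1]], h_small),
            response_nll(responses[[1]], sessions[[1]], truth))
})

test_that("compiled likelihood agrees with the R filter across rules", {
  set.seed(42)
  for (rule in c("prev", "mixture", "map_prior")) {
    h <- dpkf_hyper(alpha = runif(1, 0, 3), beta = runif(1, 0, 8),
                    q = runif(2, 0.5, 8), r = runif(2, 2, 15),
                    v = runif(2, 1, 8), decay = runif(1, 0.8, 1),
                    m0 = c(50, 50), prior_var = c(1000, 1000))
    nll_cpp <- response_nll(responses[[2]], sessions[[2]], h,
                            pred_rule = rule)
    nll_r <- 0
    for (b in 1:12) {
      tr <- run_filter(sessions[[2]]$blocks[[b]]$stimuli, h, rule)
      nll_r <- nll_r - sum(dnorm(responses[[2]]$predictions[[b]],
                                 tr$predicted,
                                 rep(sqrt(h$v), each = 18), log = TRUE))
    }
    expect_equal(nll_cpp, nll_r, tolerance = 1e-8)
  }
})

test_that("fitting is reproducible and respects the parameter box", {
  set.seed(43); f1 <- dpkf_fit(responses[[1]], sessions[[1]], "stationary_kf")
  set.seed(43); f2 <- dpkf_fit(responses[[1]], sessions[[1]], "stationary_kf")
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$train_nll, f2$train_nll)
  vs <- f1$spec
  expect_true(all(coef(f1) >= vs$lower - 1e-12 & coef(f1) <= vs$upper + 1e-12))
  expect_equal(f1$train_nll, min(f1$restart_nlls))
  expect_identical(f1$variant, "stationary_kf")
  expect_s3_class(logLik(f1), "logLik")
  expect_equal(as.numeric(logLik(f1)), -f1$train_nll)
  expect_identical(attr(logLik(f1), "df"), 5L)
})

test_that("a data-frame interface rebuilds session and responses", {
  df <- session_table(sessions[[1]], responses[[1]])
  set.seed(44); f_df <- dpkf_fit(df, variant = "stationary_kf",
                                 n_restarts = 1L)
  set.seed(44); f_ob <- dpkf_fit(responses[[1]], sessions[[1]],
                                 "stationary_kf", n_restarts = 1L)
  expect_equal(coef(f_df), coef(f_ob), tolerance = 1e-6)
})

test_that("nested variants order their training likelihoods", {
  set.seed(45)
  fits <- lapply(setNames(nm = dpkf_variants()), function(v)
    dpkf_fit(responses[[1]], sessions[[1]], v))
  nll <- vapply(fits, `[[`, numeric(1), "train_nll")
  tol <- 1e-3
  expect_lte(nll["kf"], nll["stationary_kf"] + tol)
  expect_lte(nll["stationary_dpkf"], nll["stationary_kf"] + tol)
  expect_lte(nll["dpkf"], nll["kf"] + tol)
  expect_lte(nll["dpkf"], nll["stationary_dpkf"] + tol)
  # the data come from a diffusing, segmenting agent: both restrictions bite
  expect_lt(nll["dpkf"], nll["stationary_kf"])
})

test_that("fit methods expose coefficients, predictions and residuals", {
  set.seed(46)
  fit <- dpkf_fit(responses[[1]], sessions[[1]], "kf", n_restarts = 1L)
  expect_identical(length(coef(fit)), 7L)
  preds <- predict(fit)
  expect_length(preds, 12L)
  expect_identical(dim(preds[[1]]), c(18L, 2L))
  recs <- predict(fit, type = "reconstruction")
  expect_identical(dim(recs), c(12L, 2L))
  res <- residuals(fit)
  expect_identical(dim(res), c(216L, 2L))
  expect_equal(res[1:18, ],
               responses[[1]]$predictions[[1]] - preds[[1]],
               ignore_attr = TRUE)
  set.seed(1)
  sims <- simulate(fit, nsim = 2)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "dpkf_responses")
  s <- summary(fit)
  expect_identical(unname(s$K_by_block), rep(1L, 12L))  # alpha = 0 variant
})

test_that("even/odd cross-validation trains and tests on disjoint blocks", {
  set.seed(47)
  cv <- crossval_predictive_ll(responses[[1]], sessions[[1]],
                               "stationary_kf", n_restarts = 1L)
  expect_identical(cv$folds[[1]]$train, seq(1L, 12L, 2L))
  expect_identical(cv$folds[[1]]$test, seq(2L, 12L, 2L))
  expect_identical(cv$folds[[2]]$train, seq(2L, 12L, 2L))
  expect_true(is.finite(cv$heldout_ll))
  # overfitting direction: training likelihood per block >= held-out
  expect_gt(cv$train_ll, cv$heldout_ll - 10)
})

test_that("reconstruction likelihood discriminates and saturates with noise", {
  sess <- sessions[[1]]
  # noise-free reconstructions generated by the true dpkf agent
  recs <- lapply(seq_along(sess$blocks), function(b) {
    blk <- sess$blocks[[b]]
    tr <- run_filter(blk$stimuli, truth)
    reconstruct(tr, blk$stimuli, blk$probe_t, truth)$estimate
  })
  exact <- responses[[1]]
  exact$reconstructions <- recs
  variants <- list(
    dpkf = truth,
    kf = dpkf_hyper(alpha = 0, beta = 0, q = truth$q, r = truth$r,
                    v = truth$v, m0 = truth$m0, prior_var = truth$prior_var),
    stationary_dpkf = dpkf_hyper(alpha = truth$alpha, beta = truth$beta,
                                 q = 0, r = truth$r, v = truth$v,
                                 m0 = truth$m0, prior_var = truth$prior_var),
    stationary_kf = dpkf_hyper(alpha = 0, beta = 0, q = 0, r = truth$r,
                               v = truth$v, m0 = truth$m0,
                               prior_var = truth$prior_var))
  lls <- vapply(variants, function(h)
    reconstruction_ll(exact, sess, h), numeric(1))
  expect_identical(names(which.max(lls)), "dpkf")
  # with huge response noise all variants flatten to the same constant
  flat <- vapply(variants, function(h) {
    hv <- dpkf_hyper(alpha = h$alpha, beta = h$beta, q = h$q, r = h$r,
                     v = c(1e8, 1e8), m0 = h$m0, prior_var = h$prior_var)
    reconstruction_ll(exact, sess, hv)
  }, numeric(1))
  expect_lt(diff(range(flat)), 1e-3)
})

test_that("fit results serialize to JSON", {
  set.seed(48)
  fit <- dpkf_fit(responses[[1]], sessions[[1]], "stationary_kf",
                  n_restarts = 1L)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  js <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  expect_length(js, 1L)
  expect_identical(js[[1]]$variant, "stationary_kf")
  expect_equal(js[[1]]$train_nll, fit$train_nll, tolerance = 1e-12)
})
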