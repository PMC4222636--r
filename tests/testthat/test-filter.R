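test_that("mode prediction propagates mean and grows variance with idle time", {
  h <- dpkf_hyper(q = 2, r = 1)
  p1 <- predict_mode(mode_state(3, 4, 2, 1), now = 2, hyper = h)
  expect_equal(p1$var, 6)
  expect_equal(p1$mean, 3)
  p5 <- predict_mode(mode_state(3, 4, 2, 1), now = 6, hyper = h)
  expect_equal(p5$var, 14)          # 4 + 5 * 2
  expect_equal(p5$mean, 3)          # lambda = 1 leaves the mean in place
  h0 <- dpkf_hyper(q = 0, r = 1)
  expect_equal(predict_mode(mode_state(3, 4, 2, 1), 9, h0)$var, 4)
  # decay < 1 shrinks the mean geometrically
  hd <- dpkf_hyper(q = 0, r = 1, decay = 0.5)
  expect_equal(predict_mode(mode_state(8, 4, 2, 1), 3, hd)$mean, 2)
  expect_error(predict_mode(mode_state(3, 4, 2, 5), 5, h), "exceed")
  # virtual new mode: the base measure
  pn <- predict_mode(NULL, 1, dpkf_hyper(m0 = 50, prior_var = 1000, r = 1))
  expect_equal(pn$mean, 50)
  expect_equal(pn$var, 1000)
})

test_that("Kalman gain is pred_var / (pred_var + r)", {
  expect_equal(kalman_gain(5, 5), 0.5)
  expect_equal(kalman_gain(1000, 20), 1000 / 1020)
  expect_lt(kalman_gain(1, 1e12), 1e-11)  # no learning from pure noise
  expect_error(kalman_gain(0, 1), "> 0")
  expect_error(kalman_gain(1, -1), "> 0")
})

test_that("mode update performs the error-driven conjugate step", {
  h <- dpkf_hyper(r = 20, m0 = 50, prior_var = 1000)
  st <- update_mode(NULL, 80, 1, h)
  expect_equal(st$mean, 50 + (1000 / 1020) * 30)
  expect_equal(st$var, 1000 * 20 / 1020)
  expect_identical(st$count, 1L)
  # observing the predicted mean leaves the mean, shrinks the variance
  st0 <- mode_state(10, 8, 3, 4)
  h2 <- dpkf_hyper(q = 0, r = 4)
  st1 <- update_mode(st0, 10, 5, h2)
  expect_equal(st1$mean, 10)
  expect_equal(st1$var, 8 * (1 - kalman_gain(8, 4)))
  expect_identical(st0$var, 8)     # input not mutated
  # repeated identical observations converge monotonically (q = 0)
  st <- update_mode(NULL, 0, 1, dpkf_hyper(q = 0, r = 1, m0 = 10,
                                           prior_var = 100))
  gaps <- numeric(20); vars <- numeric(20)
  for (t in 1:20) {
    gaps[t] <- abs(st$mean - 0); vars[t] <- st$var[1]
    st <- update_mode(st, 0, t + 1,
                      dpkf_hyper(q = 0, r = 1, m0 = 10, prior_var = 100))
  }
  expect_true(all(diff(gaps) <= 0) && all(diff(vars) < 0))
  expect_lt(st$var[1], 0.06)
  # closed form: posterior of a constant signal is the precision-weighted mean
  expect_equal(st$mean, (10 / 100) / (1 / 100 + 21 / 1), tolerance = 1e-10)
  expect_error(update_mode(NULL, NaN, 1, h), "finite")
})

test_that("predictive log-likelihood matches the Gaussian density", {
  h <- dpkf_hyper(q = 0, r = 1, m0 = 0, prior_var = 1)
  ll <- mode_loglik(mode_state(0, 1, 1, 1), 0, 2, h)
  expect_equal(ll, -0.5 * log(4 * pi))
  # new-mode likelihood depends only weakly on y when c is large
  hc <- dpkf_hyper(q = 0, r = 1, m0 = 0, prior_var = 1000)
  d <- abs(mode_loglik(NULL, 0, 1, hc) - mode_loglik(NULL, 10, 1, hc))
  expect_lt(d, 0.05)
  # an older mode is more tolerant of a fixed large prediction error
  ht <- dpkf_hyper(q = 1, r = 1)
  st <- mode_state(0, 1, 1, 1)
  lls <- vapply(c(2, 5, 10), function(now) mode_loglik(st, 5, now, ht),
                numeric(1))
  expect_true(all(diff(lls) > 0))
})

test_that("the first trial opens mode 1 with posterior probability 1", {
  h <- dpkf_hyper(alpha = 2, beta = 1, q = 1, r = 1, m0 = 0)
  tr <- run_filter(matrix(3.2), h)
  expect_identical(tr$z, 1L)
  expect_equal(tr$mode_posterior[[1]], 1)
  expect_equal(tr$predicted[1, ], 0)   # prior mean before any data
})

test_that("alpha = 0 reduces the DP-KF to a textbook Kalman filter", {
  set.seed(11)
  for (lam in c(1, 0.9)) {
    y <- cumsum(rnorm(100, 0, 3)) + 50
    h <- dpkf_hyper(alpha = 0, beta = 0, q = 2.5, r = 7, decay = lam,
                    m0 = 50, prior_var = 1000)
    tr <- run_filter(y, h)
    kf <- textbook_kf(y, q = 2.5, r = 7, m0 = 50, c = 1000, lambda = lam)
    expect_identical(tr$K, 1L)
    expect_lt(max(abs(tr$predicted[, 1] - kf$pred)), 1e-10)
  }
})

test_that("alpha = 0, q = 0 gives the shrinking-gain running-average filter", {
  set.seed(12)
  y <- rnorm(30, 5, 1)
  h <- dpkf_hyper(alpha = 0, beta = 0, q = 0, r = 2, m0 = 0, prior_var = 100)
  tr <- run_filter(y, h)
  # closed form: posterior after t obs is precision-weighted cumulative mean
  m_closed <- (0 / 100 + cumsum(y) / 2) / (1 / 100 + seq_along(y) / 2)
  expect_equal(tr$predicted[-1, 1], m_closed[-length(y)], tolerance = 1e-10)
})

test_that("a large jump opens a new mode and predictions catch up", {
  h <- dpkf_hyper(alpha = 1, beta = 0, q = 0.05, r = 1, m0 = 0,
                  prior_var = 1000)
  y <- c(0.0, 0.3, 0.6, 0.9, 9.0, 9.3, 9.6)
  tr <- run_filter(y, h)
  expect_identical(tr$z, c(1L, 1L, 1L, 1L, 2L, 2L, 2L))
  # one trial after the jump the prediction is near the post-jump level
  expect_lt(abs(tr$predicted[6, 1] - y[6]), 1)
  # jump magnitude far exceeds sqrt(pred var + r) on the jump trial
  expect_gt(abs(tr$prediction_error[5, 1]), 5 * sqrt(1 + 1))
})

test_that("mode posteriors normalize and the assignment is their argmax", {
  set.seed(13)
  h <- dpkf_hyper(alpha = 1.5, beta = 2, q = c(1, 1), r = c(2, 2),
                  m0 = c(0, 0), prior_var = c(100, 100))
  y <- matrix(rnorm(60, 0, 6), 30, 2)
  tr <- run_filter(y, h)
  for (t in seq_len(tr$t)) {
    p <- tr$mode_posterior[[t]]
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_identical(tr$z[t], which.max(p))
  }
  expect_identical(tr$K, length(unique(tr$z)))
  expect_identical(tr$K, length(tr$modes$count))
})

test_that("log-space likelihood survives huge prediction errors", {
  h <- dpkf_hyper(alpha = 1, beta = 0, q = 1, r = 1, m0 = 0,
                  prior_var = 1000)
  tr <- run_filter(c(0, 1e4), h)
  expect_identical(tr$z, c(1L, 2L))
  p <- tr$mode_posterior[[2]]
  expect_true(all(is.finite(p)))
  expect_lt(abs(sum(p) - 1), 1e-12)
})

test_that("new-mode probability rises with alpha and falls with beta", {
  y_hist <- c(0, 0.5, 1, 1.5)
  probe <- 8  # a moderately surprising observation
  p_new <- function(alpha, beta) {
    h <- dpkf_hyper(alpha = alpha, beta = beta, q = 0.2, r = 1, m0 = 0,
                    prior_var = 1000)
    tr <- run_filter(y_hist, h)
    tr <- filter_step(tr, probe, h)
    p <- tr$mode_posterior[[length(y_hist) + 1]]
    p[length(p)]
  }
  for (b in c(0, 2, 5)) {
    ps <- vapply(c(0.5, 1, 2, 4), p_new, numeric(1), beta = b)
    expect_true(all(diff(ps) > 0))
  }
  for (a in c(0.5, 2)) {
    ps <- vapply(c(0, 2, 5), function(b) p_new(a, b), numeric(1))
    expect_true(all(diff(ps) < 0))
  }
})

test_that("filtered mode statistics equal exact conditioning on the partition", {
  h <- dpkf_hyper(alpha = 5, beta = 0, q = 1.5, r = 2, m0 = 0,
                  prior_var = 50)
  y <- c(0.5, 8, 0.2, 9, 0.1, 8.5)
  tr <- run_filter(y, h)
  expect_gt(tr$K, 1L)
  for (mode in seq_len(tr$K)) {
    chain <- which(tr$z == mode)
    oracle <- joint_gauss_chain(chain, y[chain], q = 1.5, r = 2, c = 50,
                                m0 = 0)
    sm <- smooth_mode_chain(tr, y, mode, extra_r = 0)
    expect_lt(max(abs(sm$filtered_mean[, 1] - oracle$filtered)), 1e-8)
    # final trace statistics agree with the chain's full filtered estimate
    expect_equal(tr$modes$mean[mode, ],
                 sm$filtered_mean[length(chain), ], tolerance = 1e-10)
  }
})

test_that("filtering is deterministic and validates its inputs", {
  set.seed(14)
  h <- dpkf_hyper(alpha = 1, beta = 1, q = c(1, 1), r = c(1, 1),
                  m0 = c(0, 0))
  y <- matrix(rnorm(40), 20, 2)
  t1 <- run_filter(y, h)
  t2 <- run_filter(y, h)
  expect_identical(t1$predicted, t2$predicted)
  expect_identical(t1$z, t2$z)
  expect_error(run_filter(matrix(numeric(0), 0, 2), h), "at least one")
  expect_error(filter_step(t1, c(1, 2, 3)), "dimension mismatch")
  expect_error(run_filter(matrix(rnorm(5), 5, 1), h), "n_dims")
})

test_that("trace serialization carries predictions, modes and posteriors", {
  set.seed(15)
  h <- dpkf_hyper(alpha = 1, beta = 0, q = c(1, 1), r = c(1, 1), m0 = c(0, 0))
  y <- matrix(rnorm(20, 0, 4), 10, 2)
  tr <- run_filter(y, h)
  df <- as.data.frame(tr)
  expect_identical(nrow(df), 10L)
  expect_identical(df$map_mode, tr$z)
  p3 <- jsonlite::fromJSON(df$posterior[3])
  expect_equal(p3, tr$mode_posterior[[3]], tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".json")
  write_trace_summary(tr, path)
  js <- jsonlite::fromJSON(path)
  expect_identical(js$K, tr$K)
  expect_identical(js$assignments, tr$z)
})
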