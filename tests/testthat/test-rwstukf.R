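test_that("Mahalanobis distance is the covariance-normalised innovation energy", {
  expect_equal(mahalanobis_distance(c(0, 0), diag(2)), 0)
  expect_equal(mahalanobis_distance(c(1, 0), diag(2)), 1)
  expect_equal(mahalanobis_distance(c(1, 2), diag(c(1, 4))), 2)
  expect_error(mahalanobis_distance(c(1, 1), matrix(0, 2, 2)))
})

test_that("detection uses a strict threshold with the boundary counted consistent", {
  thr <- stats::qchisq(0.99, 2)
  expect_false(detect_model_error(thr, thr))
  expect_false(detect_model_error(0, thr))
  expect_true(detect_model_error(thr + 1e-12, thr))
  expect_equal(detection_config()$theta_T, thr)
})

test_that("random weights are a flat Dirichlet: convex, exact sum, mean 1/M", {
  expect_identical(draw_random_weights(1), 1)
  set.seed(123)
  for (M in c(2, 4, 9)) {
    for (r in 1:50) {
      v <- draw_random_weights(M)
      expect_length(v, M)
      expect_true(all(v >= 0))
      expect_lt(abs(sum(v) - 1), 1e-12)
    }
  }
  # empirical component means approach 1/M (flat-Dirichlet mean); with
  # n draws the component sd is sqrt((M-1)/(M^2(M+1)))/sqrt(n)
  set.seed(7)
  M <- 4; n <- 1e5
  draws <- replicate(n, draw_random_weights(M))
  se <- sqrt((M - 1) / (M^2 * (M + 1))) / sqrt(n)
  expect_true(all(abs(rowMeans(draws) - 1 / M) < 3 * se))
})

test_that("windowed covariance estimate matches its algebraic identities", {
  win <- innovation_window(3)
  win <- window_push(win, c(1, 0))
  expect_equal(rw_innovation_cov(win, 1), matrix(c(1, 0, 0, 0), 2))
  win <- window_push(win, c(0, 2))
  win <- window_push(win, c(1, 1))
  # equal weights reproduce the arithmetic mean of outer products
  zs <- list(c(1, 1), c(0, 2), c(1, 0))   # newest first
  manual <- Reduce(`+`, lapply(zs, tcrossprod)) / 3
  expect_equal(rw_innovation_cov(win, rep(1 / 3, 3)), manual)
  # eviction: a fourth push drops the oldest innovation
  win <- window_push(win, c(5, 5))
  expect_equal(hcukf:::window_length(win), 3)
  expect_equal(win$buffer[[1]], c(5, 5))
  expect_error(rw_innovation_cov(innovation_window(2), numeric(0)), "empty")
  # Monte-Carlo mean over random weights converges to the equal-weight value
  set.seed(99)
  acc <- matrix(0, 2, 2)
  ndraw <- 1e4
  for (i in seq_len(ndraw)) {
    acc <- acc + rw_innovation_cov(win, draw_random_weights(3))
  }
  eq <- rw_innovation_cov(win, rep(1 / 3, 3))
  expect_lt(max(abs(acc / ndraw - eq)) / max(abs(eq)), 0.01)
})

test_that("scaling factor implements the clamped trace ratio", {
  R <- diag(0.5, 2)
  # consistency case: windowed energy fully explained -> gamma 1
  sf <- scaling_factor(diag(c(2, 1)), R, diag(c(1, 1)))
  expect_equal(sf$gamma, 1)
  # direct arithmetic: (4 - 1) / 2 = 1.5
  sf2 <- scaling_factor(matrix(c(4, 0, 0, 0), 2), R, diag(1, 2))
  expect_equal(sf2$gamma_raw, 1.5)
  expect_equal(sf2$gamma, 1.5)
  # under-dispersed window clamps to 1 (never deflate)
  sf3 <- scaling_factor(diag(0.1, 2), R, diag(1, 2))
  expect_lt(sf3$gamma_raw, 0)
  expect_equal(sf3$gamma, 1)
  expect_error(scaling_factor(diag(2), R, diag(0, 2)), "positive")
  # inflation scales the covariance (and its trace) exactly
  P <- crossprod(matrix(rnorm(49), 7))
  expect_equal(corrected_covariance(P, 1), P)
  expect_equal(sum(diag(corrected_covariance(P, 2.5))), 2.5 * sum(diag(P)))
  expect_error(corrected_covariance(P, 0.5), "gamma")
})

test_that("with detection disabled the adaptive step is bitwise the plain UKF", {
  for (sc in c("init_error", "local_error")) {
    cfg <- scenario_preset(sc, seed = 3, theta_T = Inf)
    u <- run_filter_on_scenario(cfg, "ukf")
    r <- run_filter_on_scenario(cfg, "rwstukf")
    expect_identical(r$estimates, u$estimates)
    expect_identical(r$metrics$rmse, u$metrics$rmse)
    expect_false(any(r$diagnostics$corrected))
  }
})

test_that("a unit scaling factor leaves the corrected update equal to the plain one", {
  # force the corrected branch with a tiny threshold, and neutralise the
  # inflation by feeding a window whose energy implies gamma <= 1
  set.seed(31)
  cfg <- scenario_preset("init_error", seed = 31)
  noise <- noise_spec(cfg$Q, cfg$R)
  w <- ut_weights(7, cfg$alpha)
  trans <- function(X) hc_transition(X, dt = cfg$dt)
  bel <- gaussian_belief(hc_state(0.5, 0.1, 2.5, hc_params(10, 1, 2, 1.05)),
                         diag(0.01, 7))
  win <- window_push(innovation_window(4), c(1e-6, 1e-6))
  y <- c(0.52, 2.9)
  st <- rwstukf_step(bel, y, win, detection_config(theta_T = 1e-12, M = 4),
                     noise, w, trans, hc_measurement)
  plain <- ukf_step(bel, y, trans, hc_measurement, noise, w)
  expect_true(st$diagnostics$corrected)
  expect_equal(st$diagnostics$gamma, 1)
  expect_equal(st$update$posterior$mean, plain$posterior$mean,
               tolerance = 1e-12)
  expect_equal(st$update$posterior$cov, plain$posterior$cov,
               tolerance = 1e-12)
})

test_that("inflation only ever widens the posterior", {
  set.seed(8)
  cfg <- scenario_preset("local_error", seed = 8)
  r <- run_filter_on_scenario(cfg, "rwstukf")
  g <- r$diagnostics$gamma
  expect_true(all(g[!is.na(g)] >= 1))
})
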