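test_that("unscented-transform weights follow the scaled construction", {
  w <- ut_weights(7, alpha = 1, beta = 2, kappa = 0)
  expect_equal(w$lam, 0)
  expect_equal(w$wm[1], 0)
  expect_equal(w$wm[2], 1 / 14)
  expect_equal(sum(w$wm), 1)
  # beta enters only the centre covariance weight
  w0 <- ut_weights(3, alpha = 1, beta = 0, kappa = 0)
  expect_equal(w0$wc[1], w0$wm[1])
  # normalisation holds across parameterisations
  for (a in c(1, 0.5, 0.1)) {
    for (N in c(1, 4, 7)) {
      expect_equal(sum(ut_weights(N, alpha = a, kappa = 3 - N)$wm), 1)
    }
  }
  expect_error(ut_weights(7, alpha = 0), "alpha")
  expect_error(ut_weights(2, alpha = 0.1, kappa = -2), "positive")
})

test_that("sigma points bracket the mean by the scaled Cholesky factor", {
  # N = 1, lambda = 2 via alpha = 1, kappa = 2: points {0, +sqrt(3), -sqrt(3)}
  w <- ut_weights(1, alpha = 1, beta = 2, kappa = 2)
  pts <- sigma_points(gaussian_belief(0, matrix(1)), w)
  expect_equal(sort(drop(pts)), sort(c(0, sqrt(3), -sqrt(3))))
  # degenerate covariance: all points at the mean
  pts0 <- sigma_points(gaussian_belief(c(1, 2), diag(0, 2)), ut_weights(2))
  expect_true(all(pts0 == c(1, 2)))
  # weighted mean of the points reproduces the mean exactly
  set.seed(4)
  m <- rnorm(5)
  P <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  w5 <- ut_weights(5)
  expect_equal(drop(sigma_points(gaussian_belief(m, P), w5) %*% w5$wm), m)
})

test_that("prediction is exact for identity and linear dynamics", {
  w <- ut_weights(1)
  b <- gaussian_belief(0, matrix(1))
  ident <- function(X) X
  # identity dynamics, no process noise: prediction equals the belief
  pr <- ukf_predict(b, ident, matrix(0), w)
  expect_equal(pr$mean, 0)
  expect_equal(pr$cov, matrix(1))
  # 1-D linear with Q = 1: N(0,1) -> N(0,2)
  pr2 <- ukf_predict(b, ident, matrix(1), w)
  expect_equal(pr2$cov, matrix(2))
  # general linear map matches A P A' + Q to machine precision
  set.seed(9)
  A <- matrix(rnorm(16), 4)
  P <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  Q <- crossprod(matrix(rnorm(16), 4)) / 10
  m <- rnorm(4)
  pr3 <- ukf_predict(gaussian_belief(m, P), function(X) A %*% X, Q,
                     ut_weights(4))
  expect_equal(pr3$mean, drop(A %*% m), tolerance = 1e-10)
  expect_equal(pr3$cov, (A %*% P %*% t(A) + Q + t(A %*% P %*% t(A) + Q)) / 2,
               tolerance = 1e-10)
})

test_that("measurement update reproduces the closed-form Kalman update", {
  w <- ut_weights(1)
  ident <- function(X) X
  pr <- ukf_predict(gaussian_belief(0, matrix(1)), ident, matrix(1), w)
  # predicted N(0,2), H = 1, R = 1, y = 1 -> posterior mean 2/3, var 2/3
  up <- ukf_update(pr, 1, ident, matrix(1), w)
  expect_equal(up$posterior$mean, 2 / 3, tolerance = 1e-12)
  expect_equal(up$posterior$cov, matrix(2 / 3), tolerance = 1e-12)
  # zero innovation leaves the predicted mean untouched
  up0 <- ukf_update(pr, up$y_pred, ident, matrix(1), w)
  expect_equal(up0$posterior$mean, pr$mean)
})

test_that("full steps match the exact Kalman filter on a linear-Gaussian system", {
  set.seed(42)
  N <- 4
  A <- diag(0.9, N) + matrix(rnorm(N * N, sd = 0.05), N)
  H <- matrix(rnorm(2 * N), 2, N)
  Q <- diag(0.1, N)
  R <- diag(0.2, 2)
  noise <- noise_spec(Q, R)
  w <- ut_weights(N)
  m <- rnorm(N); P <- diag(1, N)
  bel <- gaussian_belief(m, P)
  km <- m; kP <- P
  x <- rnorm(N)
  for (k in 1:100) {
    x <- drop(A %*% x) + drop(chol(Q) %*% rnorm(N))
    y <- drop(H %*% x) + drop(chol(R) %*% rnorm(2))
    up <- ukf_step(bel, y, function(X) A %*% X, function(X) H %*% X,
                   noise, w)
    bel <- up$posterior
    kf <- kf_step(km, kP, y, A, H, Q, R)
    km <- kf$mean; kP <- kf$cov
    expect_lt(max(abs(bel$mean - km)), 1e-8)
    expect_lt(max(abs(bel$cov - kP)), 1e-8)
  }
})

test_that("covariances stay symmetric and conditioning never inflates them", {
  set.seed(5)
  noise <- noise_spec(diag(1e-4, 7), diag(1e-4, 2))
  w <- ut_weights(7, alpha = 0.01)
  bel <- gaussian_belief(hc_state(0.1, 0.1, 0.1, hc_params(12, 1.5, 1.8, 1.1)),
                         diag(0.05, 7))
  trans <- function(X) hc_transition(X, dt = 0.1)
  for (k in 1:50) {
    d <- 0.01 * k
    y <- c(d, 12 * d^1.8) + rnorm(2, sd = 0.01)
    up <- ukf_step(bel, y, trans, hc_measurement, noise, w)
    expect_lt(max(abs(up$posterior$cov - t(up$posterior$cov))), 1e-10)
    # linear measurement: conditioning cannot increase total variance
    expect_lte(sum(diag(up$posterior$cov)),
               sum(diag(up$prediction$cov)) + 1e-10)
    bel <- up$posterior
  }
})

test_that("steps agree with an independently coded reference UKF on the contact model", {
  set.seed(21)
  Q <- diag(1e-4, 7); R <- diag(1e-4, 2)
  noise <- noise_spec(Q, R)
  w <- ut_weights(7, alpha = 0.5)
  m <- hc_state(0.5, 0.1, 2.6, hc_params(11, 0.8, 1.9, 1.1))
  P <- diag(0.01, 7)
  bel <- gaussian_belief(m, P)
  rm_ <- m; rP <- P
  f <- function(X) hc_transition(X, dt = 0.1)
  fv <- function(x) hc_transition(x, dt = 0.1)
  hv <- function(x) unname(hc_measurement(x))
  for (k in 1:25) {
    d <- 0.5 + 0.01 * k
    y <- c(d, 11 * d^1.9) + rnorm(2, sd = 0.01)
    up <- ukf_step(bel, y, f, hc_measurement, noise, w)
    bel <- up$posterior
    ref <- ref_ukf_step(rm_, rP, y, fv, hv, Q, R, alpha = 0.5)
    rm_ <- ref$mean; rP <- ref$cov
    expect_lt(max(abs(bel$mean - rm_)), 1e-6)
    expect_lt(max(abs(bel$cov - rP)), 1e-6)
  }
})
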