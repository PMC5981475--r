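#' Gaussian state belief
#'
#' Mean/covariance pair carried by the filter.  The covariance is symmetrized
#' on construction.
#'
#' @param mean State mean vector.
#' @param cov State covariance matrix (square, conformable with \code{mean}).
#' @return Object of class \code{"gaussian_belief"}: list with \code{mean}
#'   and \code{cov}.
#' @export
gaussian_belief <- function(mean, cov) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  if (nrow(cov) != length(mean) || ncol(cov) != length(mean)) {
    stop("gaussian_belief: cov must be ", length(mean), "x", length(mean))
  }
  structure(list(mean = mean, cov = symmetrize(cov)),
            class = "gaussian_belief")
}

symmetrize <- function(M) (M + t(M)) / 2

## Solve M %*% X = B for symmetric positive-definite M whose diagonal may span
## many orders of magnitude (e.g. displacement vs force channels after a
## strong-tracking inflation).  Equilibrating to unit diagonal first keeps the
## solve well-conditioned unless M is truly singular.
solve_spd <- function(M, B) {
  s <- sqrt(diag(M))
  if (any(s <= 0) || !all(is.finite(s))) {
    stop("solve_spd: matrix has non-positive or non-finite diagonal")
  }
  Ms <- M / tcrossprod(s)
  Bs <- B / s
  (if (is.matrix(Bs)) solve(Ms, Bs) else solve(Ms, Bs)) / s
}

## Lower-triangular factor L with L %*% t(L) = M for a PSD matrix.  An exactly
## zero matrix factors to zero (degenerate belief).  On Cholesky failure a
## trace-scaled jitter is added and the factorization retried up to 3 times.
psd_sqrt <- function(M) {
  if (all(M == 0)) return(M)
  jitter <- 1e-9 * (1 + sum(abs(diag(M))) / nrow(M))
  for (attempt in 0:3) {
    Mj <- if (attempt == 0) M else M + 10^(attempt - 1) * jitter * diag(nrow(M))
    R <- tryCatch(chol(Mj), error = function(e) NULL)
    if (!is.null(R)) return(t(R))
  }
  ## Cancellation in badly scaled updates can leave sizeable negative
  ## eigenvalues; project onto the PSD cone (eigenvalue clipping) and factor.
  eg <- eigen(M, symmetric = TRUE)
  if (!all(is.finite(eg$values))) {
    stop("psd_sqrt: covariance contains non-finite values")
  }
  lam <- pmax(eg$values, jitter)
  eg$vectors %*% (sqrt(lam) * t(eg$vectors))
}

#' Unscented-transform weights
#'
#' Standard scaled unscented transform constants for an \code{N}-dimensional
#' state: \eqn{\lambda = \alpha^2 (N+\kappa) - N}, center mean weight
#' \eqn{\lambda/(N+\lambda)}, center covariance weight with the
#' \eqn{(1-\alpha^2+\beta)} correction, and \eqn{1/(2(N+\lambda))} for the
#' \eqn{2N} symmetric points.
#'
#' @param N State dimension.
#' @param alpha Spread parameter in (0, 1]; default 1.
#' @param beta Prior-distribution parameter; default 2 (Gaussian-optimal).
#' @param kappa Secondary scaling; default 0.
#' @return Object of class \code{"ut_weights"}: list with \code{N},
#'   \code{alpha}, \code{beta}, \code{kappa}, \code{lam}, mean weights
#'   \code{wm} (length 2N+1), covariance weights \code{wc}.
#' @export
ut_weights <- function(N, alpha = 1, beta = 2, kappa = 0) {
  if (N < 1) stop("ut_weights: N must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("ut_weights: alpha must be in (0, 1]")
  lam <- alpha^2 * (N + kappa) - N
  if (N + lam <= 0) stop("ut_weights: N + lambda must be positive")
  wm <- c(lam / (N + lam), rep(1 / (2 * (N + lam)), 2 * N))
  wc <- wm
  wc[1] <- wc[1] + (1 - alpha^2 + beta)
  structure(list(N = N, alpha = alpha, beta = beta, kappa = kappa,
                 lam = lam, wm = wm, wc = wc),
            class = "ut_weights")
}

#' Sigma points of a Gaussian belief
#'
#' The 2N+1 scaled sigma points: the mean, plus/minus the columns of the
#' lower Cholesky factor of \eqn{(N+\lambda) P}.  A singular covariance is
#' repaired with a small jitter before factorization; an exactly zero
#' covariance yields all points at the mean.
#'
#' @param belief A [gaussian_belief()].
#' @param weights Matching [ut_weights()].
#' @return N x (2N+1) matrix of column sigma points (column 1 = mean).
#' @export
sigma_points <- function(belief, weights) {
  N <- weights$N
  if (length(belief$mean) != N) {
    stop("sigma_points: belief dimension does not match weights")
  }
  L <- psd_sqrt((N + weights$lam) * belief$cov)
  cbind(belief$mean, belief$mean + L, belief$mean - L, deparse.level = 0)
}

## Weighted sample mean / covariance over column points.
ut_mean <- function(X, wm) drop(X %*% wm)
ut_cov <- function(devA, devB, wc) devA %*% (wc * t(devB))

#' UKF time update
#'
#' Propagates the sigma points of \code{belief} through the transition,
#' forms the predicted mean and covariance (plus process noise \code{Q}),
#' and re-draws sigma points from the predicted belief for use by the
#' measurement update.  Re-drawing after adding \code{Q} makes the unscented
#' moments exact for linear dynamics and gives the measurement update the
#' full predicted covariance (including \code{Q}) to work with.
#'
#' @param belief A [gaussian_belief()].
#' @param transition Function mapping an N-row matrix of column states to an
#'   N-row matrix (applied to all sigma points at once).
#' @param Q Process noise covariance (N x N).
#' @param weights [ut_weights()] for dimension N.
#' @return Object of class \code{"ukf_prediction"}: list with \code{mean},
#'   \code{cov} (symmetrized, includes Q), \code{sigma} (points re-drawn from
#'   the predicted belief) and \code{sigma_prop} (the propagated points).
#' @export
ukf_predict <- function(belief, transition, Q, weights) {
  X0 <- sigma_points(belief, weights)
  X <- transition(X0)
  if (!all(is.finite(X))) {
    bad <- which(!apply(is.finite(X), 2, all))[1]
    stop("ukf_predict: transition produced non-finite values at sigma point ",
         bad)
  }
  m <- ut_mean(X, weights$wm)
  dev <- X - m
  P <- symmetrize(ut_cov(dev, dev, weights$wc) + Q)
  pred <- gaussian_belief(m, P)
  structure(list(mean = pred$mean, cov = pred$cov,
                 sigma = sigma_points(pred, weights), sigma_prop = X),
            class = "ukf_prediction")
}

#' UKF measurement update
#'
#' Maps the prediction's sigma points through the measurement function,
#' forms the predicted measurement, innovation covariance (plus \code{R}),
#' state-measurement cross covariance and Kalman gain, and conditions the
#' predicted belief on the observation \code{y}.
#'
#' @param pred A [ukf_predict()] result (or any list with \code{mean},
#'   \code{cov}, \code{sigma}).
#' @param y Observed measurement vector.
#' @param measurement Function mapping an N-row matrix of column states to an
#'   m-row matrix of column measurements.
#' @param R Measurement noise covariance (m x m).
#' @param weights [ut_weights()].
#' @return Object of class \code{"ukf_update"}: list with \code{posterior}
#'   ([gaussian_belief()]), \code{innovation}, \code{innov_cov}, \code{gain},
#'   \code{cross_cov}, \code{y_pred}.
#' @export
ukf_update <- function(pred, y, measurement, R, weights) {
  Y <- measurement(pred$sigma)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = length(y))
  y_pred <- ut_mean(Y, weights$wm)
  dev_y <- Y - y_pred
  dev_x <- pred$sigma - pred$mean
  Py <- symmetrize(ut_cov(dev_y, dev_y, weights$wc) + R)
  Pxy <- ut_cov(dev_x, dev_y, weights$wc)
  K <- tryCatch(t(solve_spd(Py, t(Pxy))), error = function(e) {
    stop("ukf_update: innovation covariance is singular: ",
         conditionMessage(e))
  })
  innovation <- as.numeric(y) - y_pred
  post_mean <- pred$mean + drop(K %*% innovation)
  post_cov <- symmetrize(pred$cov - K %*% Py %*% t(K))
  structure(list(posterior = gaussian_belief(post_mean, post_cov),
                 innovation = innovation, innov_cov = Py,
                 gain = K, cross_cov = Pxy, y_pred = y_pred),
            class = "ukf_update")
}

#' One full UKF step
#'
#' [ukf_predict()] followed by [ukf_update()].  \code{pred_offset}, if given,
#' is added to the predicted state (mean and sigma points) between the two
#' half-steps; the simulator uses it to inject a transient prediction error
#' into the filter.
#'
#' @inheritParams ukf_predict
#' @inheritParams ukf_update
#' @param noise List with elements \code{Q} and \code{R} (see
#'   [noise_spec()]).
#' @param pred_offset Optional N-vector added to the predicted state.
#' @return A \code{"ukf_update"} object (with the prediction attached as
#'   \code{$prediction}).
#' @export
ukf_step <- function(belief, y, transition, measurement, noise, weights,
                     pred_offset = NULL) {
  pred <- ukf_predict(belief, transition, noise$Q, weights)
  if (!is.null(pred_offset)) {
    pred$mean <- pred$mean + pred_offset
    pred$sigma <- pred$sigma + pred_offset
  }
  upd <- ukf_update(pred, y, measurement, noise$R, weights)
  upd$prediction <- pred
  upd
}

#' Process and measurement noise covariances
#'
#' @param Q Process noise covariance (state dimension).
#' @param R Measurement noise covariance (measurement dimension).
#' @return Object of class \code{"noise_spec"}: list with \code{Q}, \code{R}.
#' @export
noise_spec <- function(Q, R) {
  Q <- as.matrix(Q); R <- as.matrix(R)
  for (M in list(Q, R)) {
    if (any(abs(M - t(M)) > 1e-12)) stop("noise_spec: covariances must be symmetric")
  }
  structure(list(Q = Q, R = R), class = "noise_spec")
}
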