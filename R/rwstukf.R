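#' Sliding window of past innovations
#'
#' Holds up to \code{M} of the most recent innovation vectors (newest first),
#' used for the random-weighted innovation-covariance estimate.  Innovations
#' from completed steps only: the current step's innovation enters the window
#' after the step finishes.
#'
#' @param M Window size (steps), at least 1.
#' @return Object of class \code{"innovation_window"}.
#' @export
innovation_window <- function(M) {
  if (M < 1) stop("innovation_window: M must be >= 1")
  structure(list(M = as.integer(M), buffer = list()),
            class = "innovation_window")
}

#' @rdname innovation_window
#' @param window An \code{"innovation_window"}.
#' @param z Innovation vector to insert (becomes the newest entry; the
#'   oldest entry is evicted once the window holds \code{M}).
#' @export
window_push <- function(window, z) {
  window$buffer <- c(list(as.numeric(z)),
                     window$buffer)[seq_len(min(window$M,
                                                length(window$buffer) + 1L))]
  window
}

window_length <- function(window) length(window$buffer)

#' Detection configuration for the adaptive filter
#'
#' @param theta_T Mahalanobis-distance threshold above which contact model
#'   error is declared.  Defaults to the \code{chi2_level} quantile of the
#'   chi-squared distribution with 2 degrees of freedom (the innovation is a
#'   2-vector), about 9.21 at the default level.
#' @param chi2_level Confidence level used to derive the default threshold.
#' @param M Innovation-window size (steps).
#' @param gamma_max Upper bound on the scaling factor applied in one step.
#'   The raw trace ratio is unbounded when the windowed innovation energy
#'   dwarfs the projected state covariance (e.g. at fault onset); capping it
#'   keeps single-step inflation finite while repeated detections still
#'   escalate geometrically.
#' @param var_max Ceiling on the inflated predicted variances (largest
#'   eigenvalue).  Scalar inflation also scales state directions the
#'   measurements cannot contract (with constant velocity the damping
#'   coefficient and velocity exponent are not separately identifiable), so
#'   consecutive detections would otherwise compound without bound.
#' @return Object of class \code{"detection_config"}.
#' @export
detection_config <- function(theta_T = NULL, chi2_level = 0.99, M = 4,
                             gamma_max = 100, var_max = 1e4) {
  if (chi2_level <= 0 || chi2_level >= 1) {
    stop("detection_config: chi2_level must be in (0, 1)")
  }
  if (is.null(theta_T)) theta_T <- stats::qchisq(chi2_level, df = 2)
  if (theta_T <= 0) stop("detection_config: theta_T must be positive")
  if (M < 1) stop("detection_config: M must be >= 1")
  if (gamma_max < 1) stop("detection_config: gamma_max must be >= 1")
  structure(list(theta_T = theta_T, chi2_level = chi2_level,
                 M = as.integer(M), gamma_max = gamma_max,
                 var_max = var_max),
            class = "detection_config")
}

## Eigenvalue clip to [0, var_max]: bounds the directions scalar inflation
## grows but measurements cannot contract.
clip_covariance <- function(P, var_max) {
  if (max(diag(P)) <= var_max && min(diag(P)) >= 0) return(P)
  eg <- eigen(P, symmetric = TRUE)
  lam <- pmin(pmax(eg$values, 0), var_max)
  symmetrize(eg$vectors %*% (lam * t(eg$vectors)))
}

#' Mahalanobis distance of an innovation
#'
#' \eqn{\theta = Z^T P_y^{-1} Z}, the squared innovation length in the metric
#' of the predicted measurement covariance.  Under a correct model this is
#' asymptotically chi-squared with as many degrees of freedom as the
#' measurement has components.
#'
#' @param innovation Innovation vector Z.
#' @param innov_cov Predicted measurement covariance.
#' @return Non-negative scalar.
#' @export
mahalanobis_distance <- function(innovation, innov_cov) {
  z <- as.numeric(innovation)
  sol <- tryCatch(solve_spd(as.matrix(innov_cov), z), error = function(e) {
    stop("mahalanobis_distance: innovation covariance is singular: ",
         conditionMessage(e))
  })
  max(drop(crossprod(z, sol)), 0)
}

#' Declare contact model error from the Mahalanobis distance
#'
#' Model error is declared strictly above the threshold; the boundary value
#' itself counts as consistent with the model.
#'
#' @param theta Mahalanobis distance (non-negative).
#' @param theta_T Threshold.
#' @return Logical flag.
#' @export
detect_model_error <- function(theta, theta_T) theta > theta_T

#' Draw random convex weights
#'
#' Flat Dirichlet over \code{M} components through the uniform-spacings
#' construction: the gaps between \code{M - 1} sorted uniforms partition the
#' unit interval.  The weights are non-negative, sum to one exactly, and have
#' mean \code{1/M} each, so the random-weighted covariance estimate is
#' unbiased relative to the equal-weight window average.
#'
#' Uses R's global RNG stream; seed with \code{set.seed()}.
#'
#' @param M Number of weights.
#' @return Numeric vector of length \code{M} summing to 1.
#' @export
draw_random_weights <- function(M) {
  if (M < 1) stop("draw_random_weights: M must be >= 1")
  if (M == 1) return(1)
  diff(c(0, sort(stats::runif(M - 1)), 1))
}

#' Random-weighted innovation covariance
#'
#' \eqn{B_0 = \sum_j v_j Z_j Z_j^T} over the windowed innovations --
#' symmetric positive semi-definite by construction.  With equal weights
#' \code{v = 1/M} this is the plain window average.
#'
#' @param window An [innovation_window()] (non-empty).
#' @param v Weight vector of length \code{window_length(window)}.
#' @return Covariance estimate (measurement dimension).
#' @export
rw_innovation_cov <- function(window, v) {
  m <- window_length(window)
  if (m == 0) stop("rw_innovation_cov: innovation window is empty")
  if (length(v) != m) {
    stop("rw_innovation_cov: need ", m, " weights, got ", length(v))
  }
  B0 <- 0
  for (j in seq_len(m)) B0 <- B0 + v[j] * tcrossprod(window$buffer[[j]])
  B0
}

#' Strong-tracking scaling factor
#'
#' Trace form derived from innovation orthogonality:
#' \deqn{\gamma = \frac{tr(B_0) - tr(R)}{tr(H \bar{P} H^T)},}
#' clamped to at least 1.  Values below 1 (deflation) arise from sampling
#' noise in \eqn{B_0} and would counteract the detector, so only inflation is
#' applied.
#'
#' @param B0 Windowed innovation-covariance estimate.
#' @param R Measurement noise covariance.
#' @param HPH Projection of the predicted state covariance into measurement
#'   space (here obtained exactly as \code{innov_cov - R}, no Jacobian
#'   needed).
#' @return List with \code{gamma} (clamped) and \code{gamma_raw}.
#' @export
scaling_factor <- function(B0, R, HPH) {
  tr_hph <- sum(diag(as.matrix(HPH)))
  if (tr_hph <= 0) {
    stop("scaling_factor: tr(H P H') must be positive, got ", tr_hph)
  }
  raw <- (sum(diag(as.matrix(B0))) - sum(diag(as.matrix(R)))) / tr_hph
  list(gamma = max(raw, 1), gamma_raw = raw)
}

#' Inflate a predicted covariance
#'
#' @param pred_cov Predicted state covariance.
#' @param gamma Scaling factor, at least 1.
#' @return \code{gamma * pred_cov}.
#' @export
corrected_covariance <- function(pred_cov, gamma) {
  if (gamma < 1) stop("corrected_covariance: gamma must be >= 1")
  gamma * pred_cov
}

#' One step of the adaptive strong-tracking UKF
#'
#' Runs the standard UKF step, computes the Mahalanobis distance of its
#' innovation, and, if model error is declared (and at least one past
#' innovation is available), estimates the innovation covariance over the
#' sliding window with random Dirichlet weights, computes the scaling
#' factor, inflates the predicted covariance, and \emph{redoes the
#' measurement update only} with sigma points re-drawn from the inflated
#' prediction.  The final innovation (from whichever update stands) is then
#' appended to the window.
#'
#' When no error is detected the step is bitwise identical to [ukf_step()].
#'
#' @inheritParams ukf_step
#' @param window [innovation_window()] of past innovations.
#' @param config [detection_config()].
#' @return List with \code{update} (a \code{"ukf_update"}), \code{window}
#'   (advanced), and \code{diagnostics}: \code{theta}, \code{gamma} (NA when
#'   no correction), \code{gamma_raw}, \code{corrected}, \code{weights_used}
#'   (the Dirichlet draw, NULL when no correction).
#' @export
rwstukf_step <- function(belief, y, window, config, noise, weights,
                         transition, measurement, pred_offset = NULL) {
  pred <- ukf_predict(belief, transition, noise$Q, weights)
  if (!is.null(pred_offset)) {
    pred$mean <- pred$mean + pred_offset
    pred$sigma <- pred$sigma + pred_offset
  }
  upd <- ukf_update(pred, y, measurement, noise$R, weights)
  theta <- mahalanobis_distance(upd$innovation, upd$innov_cov)

  corrected <- FALSE
  gamma <- NA_real_
  gamma_raw <- NA_real_
  v <- NULL
  if (detect_model_error(theta, config$theta_T) && window_length(window) > 0) {
    v <- draw_random_weights(window_length(window))
    B0 <- rw_innovation_cov(window, v)
    HPH <- upd$innov_cov - noise$R
    sf <- scaling_factor(B0, noise$R, HPH)
    gamma_cap <- if (is.null(config$gamma_max)) Inf else config$gamma_max
    gamma <- min(sf$gamma, gamma_cap)
    gamma_raw <- sf$gamma_raw
    pred$cov <- symmetrize(corrected_covariance(pred$cov, gamma))
    if (!is.null(config$var_max)) {
      pred$cov <- clip_covariance(pred$cov, config$var_max)
    }
    pred$sigma <- sigma_points(gaussian_belief(pred$mean, pred$cov), weights)
    upd <- ukf_update(pred, y, measurement, noise$R, weights)
    corrected <- TRUE
  }
  if (corrected && !is.null(config$var_max)) {
    upd$posterior$cov <- clip_covariance(upd$posterior$cov, config$var_max)
  }
  upd$prediction <- pred

  list(update = upd,
       window = window_push(window, upd$innovation),
       diagnostics = list(theta = theta, gamma = gamma,
                          gamma_raw = gamma_raw, corrected = corrected,
                          weights_used = v))
}
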