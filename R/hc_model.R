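#' Hunt-Crossley contact parameters
#'
#' Bundles the four parameters of the Hunt-Crossley viscoelastic contact law
#' \deqn{F = K d^n + B d^n \dot{d}^p,}
#' where \eqn{d} is the indentation depth and \eqn{\dot d} the indentation
#' velocity.  Units follow the indentation convention used throughout the
#' package: force in mN, displacement in mm, velocity in mm per filter step.
#'
#' Physical admissibility (\code{K >= 0}, \code{B >= 0}, \code{n > 0},
#' \code{p > 0}) is maintained by clamping rather than rejection, because
#' filter updates can transiently push parameter estimates across zero; see
#' [clamp_hc_params()].
#'
#' @param K Stiffness coefficient (mN * mm^-n).
#' @param B Damping coefficient (mN * mm^-n * (mm/step)^-p).
#' @param n Displacement exponent (dimensionless).
#' @param p Velocity exponent (dimensionless).
#'
#' @return An object of class \code{"hc_params"}: a named numeric vector
#'   \code{c(K, B, n, p)}.
#' @examples
#' hc_params(K = 10, B = 1, n = 2, p = 1.05)
#' @export
hc_params <- function(K, B, n, p) {
  v <- c(K = K, B = B, n = n, p = p)
  if (!all(is.finite(v))) {
    stop("Hunt-Crossley parameters must be finite, got: ",
         paste(sprintf("%s=%g", names(v), v), collapse = ", "))
  }
  structure(v, class = "hc_params")
}

#' Clamp Hunt-Crossley parameters to their admissible region
#'
#' Applied to the posterior state after every filter update: \code{K} and
#' \code{B} are floored at \code{1e-6}, \code{n} and \code{p} are kept in
#' \code{[1e-3, 10]}.  The floors keep \eqn{d^n} real and prevent NaN
#' propagation through sigma points when an update overshoots into negative
#' parameter values; the exponent ceiling keeps a transiently unidentified
#' exponent from overflowing \eqn{d^n} at large indentation depths
#' (physical contact exponents sit near 1-2).
#'
#' @param params An \code{"hc_params"} object or named numeric vector with
#'   elements K, B, n, p.
#' @return The clamped parameter vector (same class as input).
#' @export
clamp_hc_params <- function(params) {
  params[["K"]] <- max(params[["K"]], 1e-6)
  params[["B"]] <- max(params[["B"]], 1e-6)
  params[["n"]] <- min(max(params[["n"]], 1e-3), 10)
  params[["p"]] <- min(max(params[["p"]], 1e-3), 10)
  params
}

## Signed power: |x|^p with the sign of x.  Fractional exponents of negative
## velocities are otherwise undefined; retraction (d_dot < 0) then produces a
## force reduction of the mirrored magnitude.
signed_pow <- function(x, p) sign(x) * abs(x)^p

#' Hunt-Crossley contact force
#'
#' Evaluates \eqn{F = K d^n + B d^n \dot{d}^p}.  Displacement is clamped to
#' \code{max(d, 0)} (no tension through the contact) and the velocity power is
#' computed as \eqn{sign(\dot d)\,|\dot d|^p} so that fractional exponents
#' stay real during retraction.
#'
#' Vectorised over \code{d} and \code{d_dot}.
#'
#' @param params Hunt-Crossley parameters, see [hc_params()].
#' @param d Displacement (mm), scalar or vector.
#' @param d_dot Displacement velocity (mm/step), scalar or vector.
#' @return Contact force (mN).
#' @examples
#' hc_force(hc_params(10, 1, 2, 1.05), d = 1, d_dot = 0)   # 10
#' hc_force(hc_params(10, 1, 2, 1.05), d = 2, d_dot = 0.1) # 40.3565...
#' @export
hc_force <- function(params, d, d_dot) {
  if (!all(is.finite(d)) || !all(is.finite(d_dot))) {
    stop("hc_force: displacement and velocity must be finite")
  }
  hc_force_raw(params[["K"]], params[["B"]], params[["n"]], params[["p"]],
               d, d_dot)
}

## Unchecked core shared with the sigma-point transition.  d^n is defined as 0
## at d = 0 (even for non-positive exponents reached by stray sigma points).
hc_force_raw <- function(K, B, n, p, d, d_dot) {
  d <- pmax(d, 0)
  dn <- ifelse(d > 0, d^n, 0)
  K * dn + B * dn * signed_pow(d_dot, p)
}

#' State vector of the contact system
#'
#' The filter's joint state stacks the kinematic/kinetic variables with the
#' contact parameters: \code{[d, d_dot, F, K, B, n, p]}.
#'
#' @param d Displacement (mm).
#' @param d_dot Displacement velocity (mm/step).
#' @param F_contact Contact force (mN).
#' @param params Hunt-Crossley parameters, see [hc_params()].
#' @return Named numeric 7-vector.
#' @export
hc_state <- function(d, d_dot, F_contact, params) {
  x <- c(d = d, d_dot = d_dot, F = F_contact,
         K = params[["K"]], B = params[["B"]],
         n = params[["n"]], p = params[["p"]])
  if (!all(is.finite(x))) stop("hc_state: all components must be finite")
  x
}

hc_state_names <- c("d", "d_dot", "F", "K", "B", "n", "p")

#' State transition of the contact system
#'
#' One discrete step of the contact dynamics: displacement integrates the
#' (constant) velocity, the force component is re-evaluated from the
#' \emph{previous-step} displacement and velocity through the Hunt-Crossley
#' law, and the parameters are carried unchanged (their evolution is modelled
#' through the process noise, not the deterministic map):
#' \deqn{d' = d + \dot{d}\,\Delta t,\quad F' = K d^n + B d^n \dot{d}^p.}
#'
#' With \code{simplified = TRUE} the velocity exponent is fixed at 1
#' (\eqn{F' = K d^n + B d^n \dot d}) regardless of the state's \code{p}
#' component; this is the deliberately mis-specified filter model of the
#' model-simplification scenario.
#'
#' \code{force_at} selects the displacement at which the force is evaluated.
#' \code{"previous"} (the default, used by the filters) takes the written
#' form of the discrete state equation literally, using the pre-step
#' \eqn{d}; it carries a one-step force lag whose bias
#' \eqn{\approx K n d^{n-1} \dot d \Delta t} is negligible for gentle
#' indentation.  \code{"updated"} evaluates at \eqn{d' = d + \dot d \Delta
#' t}, removing the lag (the methods vignette discusses the trade-off).
#'
#' @param x State: a 7-vector, or a 7-row matrix of column states (the form
#'   in which sigma points are propagated).
#' @param dt Step length; defaults to 1 (one filter step).
#' @param simplified Use velocity exponent 1 in the force law.
#' @param force_at Evaluate the force at the \code{"previous"} or
#'   \code{"updated"} displacement.
#' @return Same shape as \code{x}.
#' @export
hc_transition <- function(x, dt = 1, simplified = FALSE,
                          force_at = c("previous", "updated")) {
  force_at <- match.arg(force_at)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 7) else x
  if (nrow(X) != 7) stop("hc_transition: state must have 7 components")
  p_eff <- if (simplified) 1 else X[7, ]
  Xn <- X
  Xn[1, ] <- X[1, ] + X[2, ] * dt
  d_eval <- if (force_at == "updated") Xn[1, ] else X[1, ]
  Xn[3, ] <- hc_force_raw(X[4, ], X[5, ], X[6, ], p_eff, d_eval, X[2, ])
  if (vec) {
    out <- drop(Xn)
    names(out) <- names(x)
    out
  } else Xn
}

#' Measurement function of the contact system
#'
#' The sensors observe displacement (robot encoder) and force (force sensor):
#' \eqn{y = [d, F]}, the first and third state components.  Vectorised over
#' column states.
#'
#' @param x State 7-vector or 7-row matrix of column states.
#' @return Measurement 2-vector \code{c(d, F)}, or 2-row matrix.
#' @export
hc_measurement <- function(x) {
  if (is.null(dim(x))) {
    c(d = x[[1]], F = x[[3]])
  } else {
    x[c(1, 3), , drop = FALSE]
  }
}

#' Measurement matrix
#'
#' The exact Jacobian of [hc_measurement()] -- constant, because the
#' measurement map is a linear selection of state components:
#' a 2x7 matrix with ones at (1,1) and (2,3).
#'
#' @return The 2x7 selection matrix.
#' @export
hc_measurement_matrix <- function() {
  H <- matrix(0, 2, 7, dimnames = list(c("d", "F"), hc_state_names))
  H[1, 1] <- 1
  H[2, 3] <- 1
  H
}
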