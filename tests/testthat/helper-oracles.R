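# Independent oracles for the filter tests.  Written deliberately without
# reusing any internals from R/: the closed-form Kalman filter is the exact
# reference on linear-Gaussian systems, and ref_ukf_step is a plain textbook
# unscented step (explicit loops, scalar accumulation) used to cross-check
# the package's vectorised implementation on the contact model.

# Exact Kalman filter step for x' = A x + q, y = H x + r.
kf_step <- function(m, P, y, A, H, Q, R) {
  m_pred <- A %*% m
  P_pred <- A %*% P %*% t(A) + Q
  S <- H %*% P_pred %*% t(H) + R
  K <- P_pred %*% t(H) %*% solve(S)
  m_post <- m_pred + K %*% (y - H %*% m_pred)
  P_post <- P_pred - K %*% S %*% t(K)
  list(mean = drop(m_post), cov = P_post)
}

# Textbook UKF step (scaled UT, sigma points re-drawn from the prediction
# before the measurement update), written with explicit per-point loops.
ref_ukf_step <- function(m, P, y, f, h, Q, R,
                         alpha = 1, beta = 2, kappa = 0) {
  N <- length(m)
  lam <- alpha^2 * (N + kappa) - N
  wm <- c(lam / (N + lam), rep(1 / (2 * (N + lam)), 2 * N))
  wc <- wm
  wc[1] <- wc[1] + 1 - alpha^2 + beta

  draw <- function(m, P) {
    L <- t(chol((N + lam) * P))
    pts <- matrix(0, N, 2 * N + 1)
    pts[, 1] <- m
    for (i in 1:N) {
      pts[, 1 + i] <- m + L[, i]
      pts[, 1 + N + i] <- m - L[, i]
    }
    pts
  }

  pts <- draw(m, P)
  Xp <- matrix(0, N, 2 * N + 1)
  for (i in 1:(2 * N + 1)) Xp[, i] <- f(pts[, i])
  m_pred <- rep(0, N)
  for (i in 1:(2 * N + 1)) m_pred <- m_pred + wm[i] * Xp[, i]
  P_pred <- Q
  for (i in 1:(2 * N + 1)) {
    d <- Xp[, i] - m_pred
    P_pred <- P_pred + wc[i] * (d %o% d)
  }
  P_pred <- (P_pred + t(P_pred)) / 2

  pts2 <- draw(m_pred, P_pred)
  ny <- length(y)
  Yp <- matrix(0, ny, 2 * N + 1)
  for (i in 1:(2 * N + 1)) Yp[, i] <- h(pts2[, i])
  y_pred <- rep(0, ny)
  for (i in 1:(2 * N + 1)) y_pred <- y_pred + wm[i] * Yp[, i]
  S <- R
  C <- matrix(0, N, ny)
  for (i in 1:(2 * N + 1)) {
    dy <- Yp[, i] - y_pred
    dx <- pts2[, i] - m_pred
    S <- S + wc[i] * (dy %o% dy)
    C <- C + wc[i] * (dx %o% dy)
  }
  K <- C %*% solve(S)
  m_post <- m_pred + drop(K %*% (y - y_pred))
  P_post <- P_pred - K %*% S %*% t(K)
  list(mean = m_post, cov = (P_post + t(P_post)) / 2)
}

# Small synthetic indentation CSV for the I/O tests.
write_indentation_fixture <- function(path, n = 25, velocity_col = TRUE) {
  t <- seq_len(n)
  d <- 0.05 * t
  v <- rep(0.05, n)
  F <- 10 * d^2 + d^2 * 0.05^1.05
  df <- data.frame(time = t, displacement = d, velocity = v, force = F)
  if (!velocity_col) df$velocity <- NULL
  write.csv(df, path, row.names = FALSE)
  df
}
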