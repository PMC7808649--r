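# Small numerical helpers shared across modules.

cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

interp1 <- function(x, y, xi) {
  stats::approx(x, y, xout = xi, rule = 2)$y
}

finite_gradient <- function(y, x) {
  n <- length(y)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  g
}

# Solve du/dxi = 2 g sin(alpha) - 2 (mu g + kdrag u) s'(xi) exactly by the
# integrating factor exp(2 kdrag sigma(xi)), with trapezoidal quadrature on
# the supplied grid. sigma is the cumulative path length, sp = dsigma/dxi.
energy_profile <- function(xi, sigma, sp, u0, g, alpha, mu, kdrag) {
  rhs <- 2 * g * sin(alpha) - 2 * mu * g * sp
  if (kdrag == 0) return(u0 + cumtrapz(xi, rhs))
  lf <- 2 * kdrag * sigma                 # log integrating factor
  lf <- lf - max(lf) / 2                  # centre for numerical range
  f <- exp(lf)
  (u0 * f[1] + cumtrapz(xi, f * rhs)) / f
}

# Linear-interpolated zero-crossing times of y(t), suppressing crossings
# closer than min_gap to the previously accepted one (first in a cluster
# wins). A hysteresis band proportional to the signal scale rejects sign
# flips that never leave the noise floor.
zero_crossings <- function(t, y, min_gap = 0, hysteresis = 0) {
  s <- sign(y)
  idx <- which(s[-1] * s[-length(s)] < 0)
  if (!length(idx)) return(numeric(0))
  tc <- t[idx] - y[idx] * (t[idx + 1] - t[idx]) / (y[idx + 1] - y[idx])
  if (hysteresis > 0) {
    keep <- vapply(seq_along(idx), function(j) {
      i <- idx[j]
      lo <- max(1, i - 1000); hi <- min(length(y), i + 1000)
      max(abs(y[lo:i])) >= hysteresis && max(abs(y[i:hi])) >= hysteresis
    }, logical(1))
    tc <- tc[keep]
  }
  if (min_gap > 0 && length(tc) > 1) {
    out <- tc[1]
    for (v in tc[-1]) if (v - out[length(out)] >= min_gap) out <- c(out, v)
    tc <- out
  }
  tc
}
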