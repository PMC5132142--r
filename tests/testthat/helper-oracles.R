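# Independent oracles, deliberately coded apart from the package internals.

# Tracy-Widom order-1 CDF by hand-rolled fixed-step RK4 over the Painleve II
# system (the package uses an adaptive multistep integrator instead).
# Returns a function t -> F1(t) by linear interpolation on a fine grid.
tw1_oracle <- function(lower = -9, upper = 6, h = 0.002) {
  airy <- function(x) {
    z <- (2 / 3) * x^1.5
    sqrt(x / 3) / pi * besselK(z, 1 / 3)
  }
  airy_d <- function(x) {
    z <- (2 / 3) * x^1.5
    -x / (pi * sqrt(3)) * besselK(z, 2 / 3)
  }
  t0 <- 8
  f <- function(t, s) {
    c(s[2], t * s[1] + 2 * s[1]^3, -s[1]^2, -s[3], -s[1])
  }
  state <- c(airy(t0), airy_d(t0),
             airy_d(t0)^2 - t0 * airy(t0)^2,
             integrate(function(x) (x - t0) * airy(x)^2, t0, Inf,
                       rel.tol = 1e-12)$value,
             integrate(airy, t0, Inf, rel.tol = 1e-12)$value)
  n_steps <- ceiling((t0 - lower) / h)
  ts <- numeric(n_steps + 1)
  cdf <- numeric(n_steps + 1)
  ts[1] <- t0
  cdf[1] <- exp(-(state[4] + state[5]) / 2)
  t <- t0
  for (i in seq_len(n_steps)) {
    k1 <- f(t, state)
    k2 <- f(t - h / 2, state - h / 2 * k1)
    k3 <- f(t - h / 2, state - h / 2 * k2)
    k4 <- f(t - h, state - h * k3)
    state <- state - h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t - h
    ts[i + 1] <- t
    cdf[i + 1] <- exp(-(state[4] + state[5]) / 2)
  }
  keep <- ts <= upper
  approxfun(rev(ts[keep]), rev(cdf[keep]), rule = 2)
}

# Benjamini-Hochberg step-up by direct enumeration of the definition:
# q_i = min over j with p_(j) >= p_(i) of m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# pairwise partial correlation given the covariates only, via the inverse
# of the joint covariance of (x_i, x_j, covariates)
partial_cor_oracle <- function(x, covs) {
  p <- ncol(x)
  pc <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      om <- solve(cov(cbind(x[, i], x[, j], covs)))
      pc[i, j] <- pc[j, i] <- -om[1, 2] / sqrt(om[1, 1] * om[2, 2])
    }
  }
  pc
}

# random correlation-like SPD matrix with unit diagonal
random_corr <- function(p) {
  a <- matrix(rnorm(p * (p + 2)), p + 2, p)
  s <- cov(a)
  d <- sqrt(diag(s))
  sweep(sweep(s, 1, d, "/"), 2, d, "/")
}
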