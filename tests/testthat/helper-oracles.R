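# Independent oracles used across the suite. They deliberately avoid the
# package's spectral path: trajectories come from Pade matrix exponentials,
# the oscillation-onset flux from the characteristic-polynomial discriminant.

# phi(times) by stepwise matrix-exponential propagation (arbitrary times).
oracle_output <- function(Q, pi0, g, times) {
  Qm <- unclass(Q)
  p <- pi0
  out <- numeric(length(times))
  tprev <- 0
  for (k in seq_along(times)) {
    dt <- times[k] - tprev
    if (dt > 0) p <- as.vector(p %*% as.matrix(Matrix::expm(Qm * dt)))
    tprev <- times[k]
    out[k] <- sum(p * g)
  }
  out
}

# dense trajectory on two uniform segments (fine for the response scale,
# coarse for the relaxation scale); one expm per segment, then mat-vecs.
oracle_trajectory <- function(Q, pi0, g) {
  Qm <- unclass(Q)
  re <- abs(Re(eigen(Qm, only.values = TRUE)$values))
  re <- re[re > 1e-12 * max(re)]
  t_fast <- 1 / max(re)
  t_slow <- 1 / min(re)
  seg <- function(p0, t0, dt, nstep) {
    P <- as.matrix(Matrix::expm(Qm * dt))
    p <- p0
    ts <- numeric(nstep); phi <- numeric(nstep); pm <- matrix(0, nstep, length(p0))
    for (k in seq_len(nstep)) {
      p <- as.vector(p %*% P)
      ts[k] <- t0 + k * dt
      phi[k] <- sum(p * g)
      pm[k, ] <- p
    }
    list(t = ts, phi = phi, p_end = p, p = pm)
  }
  s1 <- seg(pi0, 0, t_fast / 25, 500)           # covers 20 * t_fast
  s2 <- seg(s1$p_end, s1$t[500], t_slow / 150, 3000)  # reaches past 20 * t_slow
  list(t = c(0, s1$t, s2$t), phi = c(sum(pi0 * g), s1$phi, s2$phi),
       p = rbind(pi0, s1$p, s2$p))
}

# brute-force phase label: count visible interior extrema of the sampled
# output; overshoot requires exceeding both the initial and steady output.
oracle_classify <- function(Q, pi0, g, vis = 1e-9) {
  tr <- oracle_trajectory(Q, pi0, g)
  mu <- stationary_distribution(Q)
  phi0 <- sum(pi0 * g)
  phi_inf <- sum(mu * g)
  rng <- max(diff(range(c(tr$phi, phi_inf))), 1e-300)
  d <- diff(tr$phi)
  s <- sign(d)
  s[abs(d) < vis * rng] <- 0
  s <- s[s != 0]
  n_extrema <- if (length(s) > 1) sum(s[-length(s)] * s[-1] < 0) else 0
  pk <- max(tr$phi)
  if (n_extrema == 0 || pk <= max(phi0, phi_inf) * (1 + 1e-9) + 1e-12)
    return("NON")
  if (n_extrema >= 2) "OSCILLATORY" else "SIMPLE"
}

# discriminant of the nonzero-eigenvalue quadratic of the flux-parametrized
# three-state generator, evaluated formally (feasibility not required).
eq8_matrix_raw <- function(mu, a, b, c, J) {
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- (a + J) / (2 * mu[1]); Q[1, 3] <- (c - J) / (2 * mu[1])
  Q[2, 1] <- (a - J) / (2 * mu[2]); Q[2, 3] <- (b + J) / (2 * mu[2])
  Q[3, 1] <- (c + J) / (2 * mu[3]); Q[3, 2] <- (b - J) / (2 * mu[3])
  diag(Q) <- -rowSums(Q)
  Q
}

eq8_discriminant <- function(mu, a, b, c, J) {
  Q <- eq8_matrix_raw(mu, a, b, c, J)
  e1 <- sum(diag(Q))  # lambda1 + lambda2 (zero mode drops out)
  minor <- function(i, j) Q[i, i] * Q[j, j] - Q[i, j] * Q[j, i]
  e2 <- minor(1, 2) + minor(1, 3) + minor(2, 3)
  e1^2 - 4 * e2
}

# oscillation-onset flux by bisection on the discriminant sign change.
oracle_beta <- function(mu, a, b, c, tol = 1e-12) {
  f <- function(J) eq8_discriminant(mu, a, b, c, J)
  if (f(0) <= 0) return(0)
  hi <- 1
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e8) return(Inf)
  }
  stats::uniroot(f, lower = 0, upper = hi, tol = tol)$root
}

# random probability vector / observable helpers
random_simplex <- function(n) {
  x <- stats::rgamma(n, 1)
  x / sum(x)
}
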