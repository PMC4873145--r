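#' Random reversible (detailed-balanced) generator
#'
#' Built from random positive stationary weights \eqn{\mu} and symmetric
#' conductances \eqn{s_{ij}}: \eqn{q_{ij} = s_{ij}/\mu_i}, so
#' \eqn{\mu_i q_{ij} = s_{ij} = \mu_j q_{ji}} holds by construction and the
#' spectrum is real. Bit-reproducible for a given seed.
#'
#' @param n number of states (>= 2).
#' @param seed integer RNG seed (optional; uses the current RNG state if
#'   `NULL`).
#' @param rate_scale multiplicative scale of the rates.
#' @return a `generator`.
#' @export
random_reversible_Q <- function(n, seed = NULL, rate_scale = 1) {
  if (n < 2) stop("need at least 2 states")
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::runif(n, 0.2, 1)
  mu <- mu / sum(mu)
  S <- matrix(0, n, n)
  S[upper.tri(S)] <- stats::runif(n * (n - 1) / 2, 0.1, 1)
  S <- S + t(S)
  Q <- rate_scale * S / mu
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  validate_generator(Q)
}

#' Random driven generator with a forced cycle
#'
#' Sparse random rates plus a strong unidirectional forward cycle, producing
#' generators that frequently carry complex eigenvalues; used to exercise
#' the DDK bound and phase classification away from equilibrium.
#'
#' @inheritParams random_reversible_Q
#' @return a `generator`.
#' @export
random_driven_Q <- function(n, seed = NULL, rate_scale = 1) {
  if (n < 2) stop("need at least 2 states")
  if (!is.null(seed)) set.seed(seed)
  Q <- matrix(stats::runif(n * n, 0, rate_scale), n, n) *
    matrix(stats::rbinom(n * n, 1, 0.5), n, n)
  fwd <- c(seq(2, n), 1)
  Q[cbind(seq_len(n), fwd)] <- stats::runif(n, 0.5, 1.5) * rate_scale *
    stats::runif(1, 1, 10)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  validate_generator(Q)
}

#' Random feasible three-state flux parametrization
#'
#' Draws `mu` from a flat Dirichlet, edge sums `a`, `b`, `c` uniform on
#' `[0.2, 2]`, and `J` uniform on the feasible interval
#' `[0, min(a, b, c)]`.
#'
#' @param seed integer RNG seed (optional).
#' @return list with `params` (a [three_state_params()]) and `Q` (the built
#'   generator).
#' @export
random_eq8_Q <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::rgamma(3, 1)
  mu <- mu / sum(mu)
  # keep states from degenerating to zero mass
  mu <- 0.9 * mu + 0.1 / 3
  abc <- stats::runif(3, 0.2, 2)
  J <- stats::runif(1, 0, min(abc))
  p <- three_state_params(mu, abc[1], abc[2], abc[3], J)
  list(params = p, Q = build_three_state_Q(p))
}

#' Uniform unidirectional cycle generator
#'
#' All forward rates equal, all backward rates zero: eigenvalues
#' \eqn{q(e^{2\pi i k/n} - 1)}, the exact equality case of the DDK bound
#' \eqn{\lambda/|\omega| = \tan(\pi/n)}.
#'
#' @param n cycle length (>= 3).
#' @param rate common forward rate.
#' @return a `generator`.
#' @export
uniform_cycle_Q <- function(n, rate = 1) {
  if (n < 3) stop("a cycle needs at least 3 states")
  Q <- matrix(0, n, n)
  Q[cbind(seq_len(n), c(seq(2, n), 1))] <- rate
  diag(Q) <- -rate
  validate_generator(Q)
}
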