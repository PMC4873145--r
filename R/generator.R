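#' Validate a transition-rate (generator) matrix
#'
#' A generator matrix `Q` of a Markov jump process has nonnegative
#' off-diagonal entries (transition rates, units 1/time) and rows summing to
#' zero, so that the master equation \eqn{dp/dt = p Q} conserves probability.
#'
#' @param rates square numeric matrix of transition rates.
#' @param labels optional character vector of state names; defaults to the
#'   matrix dimnames or `"s1" ... "sN"`.
#' @param tol relative tolerance for the zero row-sum check, as a multiple of
#'   the largest absolute entry.
#' @return the validated matrix with class `"generator"` and state labels as
#'   dimnames.
#' @examples
#' validate_generator(rbind(c(-1, 1), c(2, -2)))
#' @export
validate_generator <- function(rates, labels = NULL, tol = 1e-12) {
  rates <- as.matrix(rates)
  if (!is.numeric(rates) || nrow(rates) != ncol(rates))
    stop("'rates' must be a square numeric matrix")
  n <- nrow(rates)
  if (n < 2L) stop("a generator matrix needs at least 2 states")
  if (any(!is.finite(rates))) stop("non-finite entries in rate matrix")
  scale <- max(abs(rates), 1)
  off <- rates[row(rates) != col(rates)]
  if (any(off < -tol * scale))
    stop("negative off-diagonal rate(s): a generator matrix requires q_ij >= 0 for i != j")
  # clamp harmless roundoff negatives
  rates[row(rates) != col(rates) & rates < 0] <- 0
  rs <- rowSums(rates)
  if (any(abs(rs) > tol * scale * n))
    stop(sprintf("row sums must be zero (worst deviation %.3g)", max(abs(rs))))
  diag(rates) <- diag(rates) - rs  # absorb roundoff into the diagonal
  if (is.null(labels)) {
    labels <- rownames(rates)
    if (is.null(labels)) labels <- paste0("s", seq_len(n))
  }
  if (length(labels) != n) stop("'labels' must have one name per state")
  dimnames(rates) <- list(labels, labels)
  class(rates) <- c("generator", class(rates))
  rates
}

#' @export
print.generator <- function(x, digits = 4, ...) {
  cat(sprintf("Generator matrix (%d states)\n", nrow(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

as_generator <- function(Q) {
  if (inherits(Q, "generator")) Q else validate_generator(Q)
}

# Strong connectivity of the support graph by boolean reachability.
# Returns TRUE, or the set of states not mutually reachable from state 1.
strongly_connected <- function(Q) {
  A <- (unclass(Q) > 0) | diag(nrow(Q)) > 0
  reach <- function(M) {
    R <- M
    for (i in seq_len(ceiling(log2(nrow(M))) + 1L)) R <- (R %*% R) > 0
    R
  }
  R <- reach(A)
  ok <- R[1, ] & R[, 1]
  if (all(ok)) TRUE else which(!ok)
}

#' Stationary distribution of an irreducible generator
#'
#' Solves \eqn{\mu Q = 0}, \eqn{\sum_i \mu_i = 1} exactly by the null space of
#' \eqn{Q^T} (augmented least-squares system), not by long-time integration.
#'
#' @param Q generator matrix (validated or raw).
#' @return numeric probability vector `mu` with all entries positive.
#' @export
stationary_distribution <- function(Q) {
  Q <- as_generator(Q)
  sc <- strongly_connected(Q)
  if (!isTRUE(sc))
    stop("generator is reducible: states {", paste(sc, collapse = ", "),
         "} are not mutually reachable from state 1")
  n <- nrow(Q)
  # null space of Q^T via SVD: right-singular vector of the smallest
  # singular value (robust also for stiff, weakly coupled chains)
  sv <- svd(t(unclass(Q)))
  mu <- sv$v[, n]
  mu <- mu * sign(sum(mu))
  mu[mu < 0 & mu > -1e-12] <- 0
  if (any(mu <= 0))
    stop("stationary solve produced non-positive probabilities; generator may be ill-conditioned")
  mu <- mu / sum(mu)
  names(mu) <- rownames(Q)
  mu
}

#' Validate a probability vector
#'
#' @param p nonnegative numeric vector summing to one.
#' @param n optional required length.
#' @param tol tolerance on the unit sum.
#' @return the vector, renormalized exactly.
#' @export
validate_probability <- function(p, n = NULL, tol = 1e-12) {
  p <- as.numeric(p)
  if (!is.null(n) && length(p) != n)
    stop(sprintf("probability vector must have length %d", n))
  if (any(!is.finite(p)) || any(p < -tol)) stop("probabilities must be nonnegative")
  p[p < 0] <- 0
  if (abs(sum(p) - 1) > tol * max(1, length(p)))
    stop(sprintf("probabilities must sum to 1 (got %.15g)", sum(p)))
  p / sum(p)
}

#' Stationary edge fluxes
#'
#' The net stationary probability current on each edge,
#' \eqn{J_{ij} = \mu_i q_{ij} - \mu_j q_{ji}}. For a single-cycle three-state
#' chain all three cycle-edge fluxes equal a common net flux `J`; `J = 0` on
#' every edge is the detailed balance (equilibrium) condition.
#'
#' @param Q generator matrix.
#' @param mu stationary distribution; computed from `Q` when omitted. If
#'   supplied it is checked against `Q` (error if `||mu Q||` exceeds `tol`).
#' @param tol stationarity tolerance, relative to the largest rate.
#' @return antisymmetric numeric matrix of edge fluxes.
#' @export
edge_fluxes <- function(Q, mu = NULL, tol = 1e-8) {
  Q <- as_generator(Q)
  if (is.null(mu)) {
    mu <- stationary_distribution(Q)
  } else {
    mu <- validate_probability(mu, nrow(Q))
    resid <- max(abs(mu %*% unclass(Q)))
    if (resid > tol * max(abs(Q), 1))
      stop(sprintf("'mu' is not stationary for Q (||mu Q|| = %.3g)", resid))
  }
  M <- mu * unclass(Q)   # M_ij = mu_i q_ij
  J <- M - t(M)
  diag(J) <- 0
  J
}

# BFS spanning tree of the undirected support graph; returns parent vector.
support_tree <- function(Q) {
  n <- nrow(Q)
  A <- (unclass(Q) > 0) | t(unclass(Q) > 0)
  parent <- rep(NA_integer_, n)
  seen <- c(TRUE, rep(FALSE, n - 1))
  queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(A[v, ] & !seen)
    parent[nb] <- v
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  parent
}

tree_path <- function(parent, v) {
  path <- v
  while (!is.na(parent[v])) { v <- parent[v]; path <- c(path, v) }
  path
}

# log of (product of forward rates / product of backward rates) along a cycle
# given as a closed vector of states; Inf if a backward rate is zero.
cycle_log_ratio <- function(Q, cyc) {
  Q <- unclass(Q)
  lf <- lb <- 0
  for (k in seq_len(length(cyc) - 1)) {
    i <- cyc[k]; j <- cyc[k + 1]
    lf <- lf + log(Q[i, j])
    lb <- lb + log(Q[j, i])
  }
  lf - lb
}

#' Detailed balance (equilibrium) test
#'
#' A stationary Markov chain is in equilibrium iff \eqn{\mu_i q_{ij} = \mu_j
#' q_{ji}} for every pair of states, equivalently (Kolmogorov's criterion) iff
#' the product of rates along every cycle equals that along the reversed
#' cycle. The worst-violating cycle is identified among the fundamental
#' cycles of a spanning tree of the support graph.
#'
#' @param Q generator matrix.
#' @param tol relative tolerance on the flux balance.
#' @return list with `balanced` (logical), `max_violation` (largest
#'   \eqn{|\mu_i q_{ij} - \mu_j q_{ji}|} relative to the largest edge
#'   probability flow), `worst_cycle` (integer state sequence, closed) and
#'   `worst_log_ratio` (log forward/backward rate-product ratio, possibly
#'   `Inf` for one-way cycles).
#' @export
is_detailed_balanced <- function(Q, tol = 1e-9) {
  Q <- as_generator(Q)
  mu <- stationary_distribution(Q)
  M <- mu * unclass(Q)
  viol <- max(abs(M - t(M))) / max(M[row(M) != col(M)], .Machine$double.xmin)
  balanced <- viol <= tol

  # fundamental cycles from a BFS spanning tree
  parent <- support_tree(Q)
  n <- nrow(Q)
  worst <- list(cycle = integer(0), lr = 0)
  tree_edge <- matrix(FALSE, n, n)
  for (v in which(!is.na(parent))) {
    tree_edge[v, parent[v]] <- tree_edge[parent[v], v] <- TRUE
  }
  A <- (unclass(Q) > 0) | t(unclass(Q) > 0)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (!A[i, j] || tree_edge[i, j]) next
    pi_ <- tree_path(parent, i); pj <- tree_path(parent, j)
    common <- intersect(pi_, pj)
    anc <- common[which.min(match(common, pi_))]
    ki <- match(anc, pi_); kj <- match(anc, pj)
    # closed cycle i -> ... -> anc -> ... -> j -> i (last hop is the chord)
    cyc <- c(pi_[seq_len(ki)], rev(pj[seq_len(kj - 1)]), i)
    if (length(cyc) < 4) next  # 2-cycles always balance in rate products
    lr <- cycle_log_ratio(Q, cyc)
    if (!is.finite(lr) || abs(lr) > abs(worst$lr)) {
      worst <- list(cycle = cyc, lr = lr)
      if (!is.finite(lr)) break
    }
  }
  list(balanced = balanced, max_violation = viol,
       worst_cycle = worst$cycle, worst_log_ratio = worst$lr)
}

#' Confirm the real spectrum of a reversible generator
#'
#' For a detailed-balanced generator the similarity transform
#' \eqn{S = M Q M^{-1}} with \eqn{M = diag(\sqrt{\mu_i})} is symmetric, so
#' all eigenvalues of `Q` are real. This check builds `S`, verifies its
#' symmetry, and confirms that no eigenvalue of `Q` has an imaginary part
#' above tolerance.
#'
#' @param Q a detailed-balanced generator (error otherwise).
#' @param tol imaginary-part tolerance.
#' @return `TRUE` if the spectrum is real within `tol`, else `FALSE`.
#' @export
reversible_spectrum_check <- function(Q, tol = 1e-9) {
  Q <- as_generator(Q)
  db <- is_detailed_balanced(Q)
  if (!db$balanced)
    stop("reversible_spectrum_check() requires a detailed-balanced generator")
  mu <- stationary_distribution(Q)
  d <- sqrt(mu)
  S <- d * unclass(Q) * rep(1 / d, each = length(d))
  if (max(abs(S - t(S))) > 1e-10 * max(abs(S)))
    stop("symmetrized matrix is not symmetric; detailed balance violated numerically")
  ev <- eigen(unclass(Q), only.values = TRUE)$values
  all(abs(Im(ev)) <= tol * pmax(1, abs(ev)))
}

# module-wide rule: an eigenvalue is complex iff |Im| > 1e-9 * max(1, |lambda|)
is_complex_ev <- function(lambda, tol = 1e-9) {
  abs(Im(lambda)) > tol * pmax(1, abs(lambda))
}

#' Count complex eigenvalues of a generator
#'
#' Uses the package-wide realness rule: an eigenvalue counts as complex iff
#' \eqn{|Im \lambda| > 10^{-9} \max(1, |\lambda|)} (numerical noise on
#' real-spectrum matrices is several orders smaller).
#'
#' @param Q generator matrix.
#' @return even integer (complex eigenvalues come in conjugate pairs).
#' @export
n_complex_eigenvalues <- function(Q) {
  ev <- eigen(unclass(as_generator(Q)), only.values = TRUE)$values
  sum(is_complex_ev(ev))
}

#' Dmitriev-Dynkin-Karpelevich ratio of a generator spectrum
#'
#' Every conjugate pair \eqn{-\lambda \pm i\omega} of complex eigenvalues of
#' an N-state generator satisfies \eqn{\lambda/|\omega| \ge \tan(\pi/N)},
#' with equality iff the chain is a unidirectional cycle with equal forward
#' rates. The ratio bounds how many oscillation periods can be seen before
#' the mode has decayed.
#'
#' @param Q generator matrix.
#' @return list with `min_ratio` (minimum \eqn{\lambda/|\omega|} over complex
#'   pairs, `Inf` for a real spectrum), `bound` (\eqn{\tan(\pi/N)}),
#'   `n_states`, and `satisfied`.
#' @export
ddk_bound <- function(Q) {
  Q <- as_generator(Q)
  n <- nrow(Q)
  ev <- eigen(unclass(Q), only.values = TRUE)$values
  cx <- ev[is_complex_ev(ev)]
  ratio <- if (length(cx)) min(-Re(cx) / abs(Im(cx))) else Inf
  bound <- tan(pi / n)
  list(min_ratio = ratio, bound = bound, n_states = n,
       satisfied = ratio >= bound - 1e-9)
}

#' Spectral and equilibrium diagnostics of a generator
#'
#' @param Q generator matrix.
#' @return list ready for JSON serialization: `eigenvalues_re`,
#'   `eigenvalues_im`, `n_complex`, `ddk_min_ratio`, `detailed_balanced`,
#'   `worst_cycle`.
#' @export
generator_diagnostics <- function(Q) {
  Q <- as_generator(Q)
  ev <- eigen(unclass(Q), only.values = TRUE)$values
  db <- is_detailed_balanced(Q)
  list(eigenvalues_re = Re(ev), eigenvalues_im = Im(ev),
       n_complex = sum(is_complex_ev(ev)),
       ddk_min_ratio = ddk_bound(Q)$min_ratio,
       detailed_balanced = db$balanced,
       worst_cycle = db$worst_cycle)
}
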