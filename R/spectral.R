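#' Spectral decomposition of a master-equation output
#'
#' For a Markov jump process with generator `Q`, initial distribution `pi0`
#' and observable `g`, the output \eqn{\phi(t) = p(t) g^T} with
#' \eqn{p(t) = \pi_0 e^{Qt}} expands over the eigenmodes of `Q` as
#' \deqn{\phi(t) = \phi_\infty + \sum_{i=1}^{N-1} c_i e^{\lambda_i t},}
#' where \eqn{\lambda_i} are the nonzero eigenvalues (all with negative real
#' part, one eigenvalue being exactly zero by Perron-Frobenius) and the mode
#' coefficients are \eqn{c_i = (\pi_0 V)_i (V^{-1} g)_i} for the
#' eigendecomposition \eqn{Q = V \Lambda V^{-1}}. Complex eigenvalues and
#' coefficients come in conjugate pairs, so \eqn{\phi(t)} is real; each pair
#' \eqn{-\lambda \pm i\omega} contributes a damped cosine
#' \eqn{2|c| e^{-\lambda t} \cos(\omega t + \arg c)}.
#'
#' If the eigenvalue spectrum is nearly degenerate (pairwise gap below
#' `degenerate_tol` times the spectral radius) the expansion is abandoned and
#' the object falls back to direct matrix-exponential propagation
#' (`mode = "propagator"`); trajectory evaluation and peak finding then work
#' on \eqn{\pi_0 e^{Qt} g^T} instead.
#'
#' @param Q generator matrix (see [validate_generator()]); must be
#'   irreducible.
#' @param pi0 initial probability distribution.
#' @param g numeric observable, one value per state.
#' @param degenerate_tol relative eigenvalue-gap threshold below which the
#'   spectral construction is abandoned.
#' @return an object of class `"spectral_response"` with components
#'   `eigenvalues` (nonzero modes, sorted by decreasing real part),
#'   `coefficients` (matching \eqn{c_i}), `phi_inf`, `phi0`, `mu`,
#'   `mode` (`"spectral"` or `"propagator"`), `modes` (a data frame with one
#'   row per mode giving decay rate, angular frequency and cosine phase), and
#'   the inputs `Q`, `pi0`, `g`.
#' @seealso [predict.spectral_response()], [find_peak()], [classify_phase()]
#' @examples
#' Q <- validate_generator(rbind(c(-1, 1), c(2, -2)))
#' r <- spectral_response(Q, pi0 = c(1, 0), g = c(0, 1))
#' r$phi_inf          # 1/3
#' r$eigenvalues      # -3
#' predict(r, c(0, 1, 10))
#' @export
spectral_response <- function(Q, pi0, g, degenerate_tol = 1e-8) {
  Q <- as_generator(Q)
  n <- nrow(Q)
  pi0 <- validate_probability(pi0, n)
  g <- as.numeric(g)
  if (length(g) != n || any(!is.finite(g)))
    stop("'g' must be a finite numeric observable with one value per state")
  mu <- stationary_distribution(Q)
  phi0 <- sum(pi0 * g)
  phi_inf <- sum(mu * g)

  ee <- eigen(unclass(Q))
  lam <- ee$values
  # Perron-Frobenius: snap the minimum-modulus eigenvalue to exactly 0
  izero <- which.min(abs(lam))
  radius <- max(abs(lam))
  gaps <- abs(outer(lam, lam, "-"))
  mingap <- min(gaps[upper.tri(gaps)])

  out <- list(Q = Q, pi0 = pi0, g = g, mu = mu,
              phi0 = phi0, phi_inf = phi_inf, n_states = n)

  if (mingap < degenerate_tol * max(radius, .Machine$double.xmin)) {
    out$mode <- "propagator"
    out$eigenvalues <- lam[-izero]
    out$coefficients <- rep(NA_complex_, n - 1)
    out$modes <- NULL
    class(out) <- "spectral_response"
    return(out)
  }

  V <- ee$vectors
  cs <- as.vector(pi0 %*% V) * as.vector(solve(V, as.complex(g)))
  lam[izero] <- 0
  c0 <- cs[izero]
  if (abs(Im(c0)) > 1e-8 * max(1, abs(c0)))
    stop("zero-mode coefficient has a large imaginary part; decomposition failed")
  lam_nz <- lam[-izero]
  cs_nz <- cs[-izero]
  ord <- order(-Re(lam_nz), abs(Im(lam_nz)))
  lam_nz <- lam_nz[ord]
  cs_nz <- cs_nz[ord]

  # reconstruction sanity: phi(0) = phi_inf + sum(c_i)
  if (abs(phi_inf + sum(Re(cs_nz)) - phi0) > 1e-6 * max(1, abs(phi0)))
    stop("spectral reconstruction of phi(0) failed; matrix may be near-defective")

  cxp <- is_complex_ev(lam_nz)
  out$mode <- "spectral"
  out$eigenvalues <- lam_nz
  out$coefficients <- cs_nz
  out$modes <- data.frame(
    re = Re(lam_nz), im = Im(lam_nz),
    decay = -Re(lam_nz), omega = abs(Im(lam_nz)),
    amplitude = ifelse(cxp, 2 * Mod(cs_nz), Re(cs_nz)),
    phase = ifelse(cxp, Arg(cs_nz), 0),
    complex = cxp)
  class(out) <- "spectral_response"
  out
}

#' Default evaluation time grid for a response
#'
#' 400 log-spaced points from `1e-3 * t_fast` to `20 * t_slow`, where
#' `t_fast` and `t_slow` are the inverse real parts of the fastest and
#' slowest nonzero eigenvalues, so both the response and the relaxation
#' scale are resolved.
#'
#' @param resp a `spectral_response`.
#' @param n number of grid points.
#' @return increasing numeric vector of times.
#' @export
default_time_grid <- function(resp, n = 400) {
  re <- abs(Re(resp$eigenvalues))
  re <- re[re > 0]
  t_fast <- 1 / max(re)
  t_slow <- 1 / min(re)
  exp(seq(log(1e-3 * t_fast), log(20 * t_slow), length.out = n))
}

#' Evaluate the output trajectory
#'
#' @param object a `spectral_response`.
#' @param times nonnegative evaluation times.
#' @param ... unused.
#' @return numeric vector \eqn{\phi(times)}; the imaginary residue of the
#'   mode sum (below 1e-10 by conjugate pairing) is discarded.
#' @export
predict.spectral_response <- function(object, times = default_time_grid(object), ...) {
  times <- as.numeric(times)
  if (any(times < 0)) stop("negative times are not allowed")
  if (object$mode == "propagator") {
    return(propagate_output(object$Q, object$pi0, object$g, times))
  }
  E <- exp(outer(times, object$eigenvalues))   # |times| x (N-1)
  vals <- as.vector(E %*% object$coefficients) + object$phi_inf
  if (length(vals) && max(abs(Im(vals))) > 1e-8 * max(1, max(abs(vals))))
    warning("non-negligible imaginary residue discarded from output trajectory")
  Re(vals)
}

#' @rdname predict.spectral_response
#' @param resp a `spectral_response`.
#' @export
output_trajectory <- function(resp, times) {
  stopifnot(inherits(resp, "spectral_response"))
  predict(resp, times)
}

# Direct matrix-exponential propagation of the output (scaling-and-squaring
# expm); used as the fallback mode for near-degenerate spectra.
propagate_output <- function(Q, pi0, g, times) {
  Q <- unclass(as_generator(Q))
  ord <- order(times)
  ts <- times[ord]
  p <- pi0
  out <- numeric(length(ts))
  tprev <- 0
  for (k in seq_along(ts)) {
    dt <- ts[k] - tprev
    if (dt > 0) p <- as.vector(p %*% as.matrix(Matrix::expm(Q * dt)))
    tprev <- ts[k]
    out[k] <- sum(p * g)
  }
  out[order(ord)]
}

#' @export
coef.spectral_response <- function(object, ...) {
  data.frame(eigenvalue = object$eigenvalues, coefficient = object$coefficients)
}

#' @export
print.spectral_response <- function(x, ...) {
  cat(sprintf("Spectral response (%d states, mode = %s)\n", x$n_states, x$mode))
  cat(sprintf("  phi0 = %.6g, phi_inf = %.6g\n", x$phi0, x$phi_inf))
  if (x$mode == "spectral") {
    ncx <- sum(x$modes$complex)
    cat(sprintf("  %d relaxation mode(s), %d complex\n",
                length(x$eigenvalues), ncx))
    print(x$modes, digits = 5)
  } else {
    cat("  near-degenerate spectrum: trajectory by matrix-exponential propagation\n")
  }
  invisible(x)
}

#' @export
summary.spectral_response <- function(object, ...) {
  pre <- check_response_preconditions(object)
  pk <- find_peak(object)
  structure(list(response = object, preconditions = pre, peak = pk,
                 phase = classify_phase(object)),
            class = "summary.spectral_response")
}

#' @export
print.summary.spectral_response <- function(x, ...) {
  print(x$response)
  cat(sprintf("  phi'(0) > 0: %s;  phi_inf >= phi0: %s\n",
              x$preconditions$slope0_positive, x$preconditions$steady_ge_initial))
  if (x$peak$interior)
    cat(sprintf("  interior peak phi = %.6g at t = %.6g\n",
                x$peak$phi_peak, x$peak$t_peak))
  else cat("  no interior peak (monotone output)\n")
  cat(sprintf("  phase: %s\n", x$phase))
  invisible(x)
}

#' Plot a response trajectory
#'
#' @param x a `spectral_response`.
#' @param times evaluation grid (default [default_time_grid()]).
#' @param log axis spec passed to [graphics::plot()] (default log-time).
#' @param ... further plot arguments.
#' @export
plot.spectral_response <- function(x, times = default_time_grid(x), log = "x", ...) {
  phi <- predict(x, times)
  graphics::plot(times, phi, type = "l", log = log,
                 xlab = "time", ylab = expression(phi(t)), ...)
  graphics::abline(h = c(x$phi0, x$phi_inf), lty = c(3, 2), col = "grey40")
}
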