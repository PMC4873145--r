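#' Step protocol for an input stimulus
#'
#' The input level is elevated from `I0` to `I1` at time 0; the initial
#' distribution is the stationary distribution at `I0` and the dynamics after
#' the step are governed by the generator at `I1`.
#'
#' @param I0,I1 input levels with `I1 > I0 > 0`.
#' @return list of class `"step_protocol"`.
#' @export
step_protocol <- function(I0, I1) {
  if (!(I1 > I0 && I0 > 0)) stop("a step protocol requires I1 > I0 > 0")
  structure(list(I0 = I0, I1 = I1, step_time = 0), class = "step_protocol")
}

#' Check the standard response preconditions
#'
#' Transient-response analysis assumes the output initially rises,
#' \eqn{\phi'(0) > 0}, and relaxes to a steady value at least as large as the
#' initial one, \eqn{\phi_\infty \ge \phi_0}. The initial slope is computed
#' analytically as \eqn{\pi_0 Q g^T} (equivalently \eqn{\sum_i c_i
#' \lambda_i}). The flags are reported, not enforced.
#'
#' @param resp a `spectral_response`.
#' @return list with `slope0`, `slope0_positive`, `steady_ge_initial`.
#' @export
check_response_preconditions <- function(resp) {
  stopifnot(inherits(resp, "spectral_response"))
  slope0 <- as.numeric(resp$pi0 %*% unclass(resp$Q) %*% resp$g)
  list(slope0 = slope0,
       slope0_positive = slope0 > 0,
       steady_ge_initial = resp$phi_inf >= resp$phi0 - 1e-12 * max(1, abs(resp$phi0)))
}

# derivative of the mode expansion, vectorized over t
.dphi <- function(resp, t) {
  E <- exp(outer(t, resp$eigenvalues))
  Re(as.vector(E %*% (resp$coefficients * resp$eigenvalues)))
}

#' Locate the output peak
#'
#' Finds the global maximum of \eqn{\phi(t)} on \eqn{t \in (0, \infty)}. For
#' spectral-mode responses, sign changes of the analytic derivative
#' \eqn{\phi'(t) = \sum_i c_i \lambda_i e^{\lambda_i t}} are bracketed on the
#' default log grid and refined by root finding to relative tolerance 1e-10;
#' for oscillatory responses all local maxima inside the decaying envelope
#' are compared (ties resolve to the earliest time). For a propagator-mode
#' response the grid maximum is refined with [stats::optimize()].
#'
#' @param resp a `spectral_response`.
#' @param grid time grid used for bracketing (default [default_time_grid()]).
#' @return list with `t_peak`, `phi_peak` and `interior` (`FALSE` for a
#'   monotone output, in which case `t_peak = Inf` and
#'   `phi_peak = phi_inf` for a rising output).
#' @export
find_peak <- function(resp, grid = default_time_grid(resp)) {
  stopifnot(inherits(resp, "spectral_response"))
  grid <- c(0, grid)

  if (resp$mode == "propagator") {
    phi <- predict(resp, grid)
    k <- which.max(phi)
    if (k == 1L || k == length(grid)) {
      rising <- phi[length(phi)] >= phi[1]
      return(list(t_peak = if (rising) Inf else 0,
                  phi_peak = if (rising) resp$phi_inf else resp$phi0,
                  interior = FALSE))
    }
    opt <- stats::optimize(function(t) predict(resp, t),
                           lower = grid[k - 1], upper = grid[k + 1],
                           maximum = TRUE, tol = 1e-10 * grid[k + 1])
    return(list(t_peak = opt$maximum, phi_peak = opt$objective, interior = TRUE))
  }

  ds <- .dphi(resp, grid)
  sgn <- sign(ds)
  idx <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  roots <- numeric(0)
  for (i in idx) {
    r <- stats::uniroot(function(t) .dphi(resp, t),
                        lower = grid[i], upper = grid[i + 1],
                        tol = 1e-10 * max(grid[i + 1], 1e-300))$root
    roots <- c(roots, r)
  }
  # local maxima: derivative goes + -> -
  maxima <- roots[sgn[idx] > 0]
  if (!length(maxima)) {
    rising <- ds[1] > 0 || resp$phi_inf >= resp$phi0
    return(list(t_peak = if (rising) Inf else 0,
                phi_peak = if (rising) resp$phi_inf else resp$phi0,
                interior = FALSE))
  }
  vals <- predict(resp, maxima)
  best <- max(vals)
  k <- which(vals >= best - 1e-12 * max(1, abs(best)))[1]  # earliest of ties
  list(t_peak = maxima[k], phi_peak = vals[k], interior = TRUE)
}

# overshoot rule: strict exceedance guarded against roundoff
has_overshoot <- function(phi_peak, phi0, phi_inf) {
  phi_peak > max(phi0, phi_inf) * (1 + 1e-9) + 1e-12
}

#' Classify a response as NON, SIMPLE or OSCILLATORY
#'
#' A response performs overshoot when its interior peak exceeds both the
#' initial and the steady-state output. Overshoot with only real relaxation
#' modes contributing to the observable is *simple*; overshoot carried by at
#' least one conjugate complex mode with coefficient magnitude above
#' `tol_coeff` is *oscillatory* (the observable can be blind to complex
#' modes, in which case the output is not oscillatory even if the spectrum
#' is). A two-state system is always `NON` since its output is monotone.
#'
#' @param resp a `spectral_response`.
#' @param tol_coeff visibility threshold on \eqn{|c_i|}; defaults to
#'   `1e-12 * (max g - min g)`.
#' @return one of `"NON"`, `"SIMPLE"`, `"OSCILLATORY"`.
#' @export
classify_phase <- function(resp, tol_coeff = NULL) {
  stopifnot(inherits(resp, "spectral_response"))
  if (is.null(tol_coeff)) {
    sc <- diff(range(resp$g))
    tol_coeff <- 1e-12 * if (sc > 0) sc else 1
  }

  if (resp$mode == "propagator") return(classify_by_trajectory(resp))

  pk <- find_peak(resp)
  if (!pk$interior || !has_overshoot(pk$phi_peak, resp$phi0, resp$phi_inf))
    return("NON")
  visible_complex <- any(is_complex_ev(resp$eigenvalues) &
                           Mod(resp$coefficients) > tol_coeff)
  if (visible_complex) "OSCILLATORY" else "SIMPLE"
}

# trajectory-shape fallback for near-degenerate spectra: count visible
# interior extrema of the propagated output
classify_by_trajectory <- function(resp, grid = default_time_grid(resp, 800)) {
  phi <- predict(resp, grid)
  rng <- max(diff(range(phi)), 1e-300)
  d <- diff(phi)
  s <- sign(d)
  s[abs(d) < 1e-9 * rng] <- 0
  s <- s[s != 0]
  n_extrema <- sum(s[-length(s)] * s[-1] < 0)
  pk <- max(phi)
  if (n_extrema == 0 || !has_overshoot(pk, resp$phi0, resp$phi_inf)) return("NON")
  if (n_extrema >= 2) "OSCILLATORY" else "SIMPLE"
}

#' Adaptation performance metrics
#'
#' For a step of the input from `I0` to `I1` the adaptation sensitivity and
#' error are the normalized peak response and residual offset,
#' \deqn{\gamma = \frac{(\phi_{peak}-\phi_0)/\phi_0}{(I_1-I_0)/I_0}, \qquad
#'       \epsilon = \frac{(\phi_\infty-\phi_0)/\phi_0}{(I_1-I_0)/I_0},}
#' the accuracy is \eqn{\delta = 1/\epsilon} (reported as `Inf` for perfect
#' adaptation, \eqn{\epsilon = 0}), and the adaptation efficiency is the
#' input-independent ratio
#' \deqn{\eta = 1 - \epsilon/\gamma = (\phi_{peak}-\phi_\infty) /
#'       (\phi_{peak}-\phi_0) \in [0, 1].}
#' \eqn{\gamma, \epsilon, \delta} require a protocol and \eqn{\phi_0 \ne 0};
#' \eqn{\eta} is defined whenever \eqn{\phi_{peak} > \phi_0}.
#'
#' @param phi0 initial output.
#' @param phi_peak peak output.
#' @param phi_inf steady-state output.
#' @param protocol optional [step_protocol()].
#' @param t_peak optional peak time (carried through).
#' @param phase optional phase label (carried through).
#' @return object of class `"adaptation_metrics"`: list with `phi0`,
#'   `phi_peak`, `t_peak`, `phi_inf`, `gamma`, `epsilon`, `delta`, `eta`,
#'   `phase` (undefined quantities are `NA`).
#' @examples
#' adaptation_metrics(1, 1.8, 1.2, step_protocol(10, 15))
#' @export
adaptation_metrics <- function(phi0, phi_peak, phi_inf, protocol = NULL,
                               t_peak = NA_real_, phase = NA_character_) {
  gamma <- epsilon <- delta <- NA_real_
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "step_protocol"))
    if (phi0 != 0) {
      rel <- (protocol$I1 - protocol$I0) / protocol$I0
      gamma <- ((phi_peak - phi0) / phi0) / rel
      epsilon <- ((phi_inf - phi0) / phi0) / rel
      delta <- if (epsilon == 0) Inf else 1 / epsilon
    }
  }
  eta <- if (phi_peak > phi0) (phi_peak - phi_inf) / (phi_peak - phi0) else NA_real_
  structure(list(phi0 = phi0, phi_peak = phi_peak, t_peak = t_peak,
                 phi_inf = phi_inf, gamma = gamma, epsilon = epsilon,
                 delta = delta, eta = eta, phase = phase),
            class = "adaptation_metrics")
}

#' Full adaptation analysis of a response
#'
#' Convenience wrapper: locates the peak, classifies the phase and computes
#' the adaptation metrics of a `spectral_response` in one call.
#'
#' @param resp a `spectral_response`.
#' @param protocol optional [step_protocol()] (enables gamma/epsilon/delta).
#' @return an `"adaptation_metrics"` object.
#' @export
adaptation_summary <- function(resp, protocol = NULL) {
  pk <- find_peak(resp)
  phase <- classify_phase(resp)
  adaptation_metrics(resp$phi0, pk$phi_peak, resp$phi_inf, protocol,
                     t_peak = pk$t_peak, phase = phase)
}

#' @export
print.adaptation_metrics <- function(x, ...) {
  cat("Adaptation metrics\n")
  cat(sprintf("  phi0 = %.6g, phi_peak = %.6g (t = %.6g), phi_inf = %.6g\n",
              x$phi0, x$phi_peak, x$t_peak, x$phi_inf))
  cat(sprintf("  gamma = %.6g, epsilon = %.6g, delta = %.6g, eta = %.6g\n",
              x$gamma, x$epsilon, x$delta, x$eta))
  cat(sprintf("  phase: %s\n", x$phase))
  invisible(x)
}

#' @export
as.data.frame.adaptation_metrics <- function(x, ...) {
  data.frame(phi0 = x$phi0, phi_peak = x$phi_peak, t_peak = x$t_peak,
             phi_inf = x$phi_inf, gamma = x$gamma, epsilon = x$epsilon,
             delta = x$delta, eta = x$eta, phase = x$phase)
}
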