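#' Parameters of the MCP receptor sensory network model
#'
#' The ten-state model of an E. coli methyl-accepting chemotaxis protein
#' (MCP) receptor: a binary activity \eqn{a \in \{0, 1\}} and a methylation
#' level \eqn{m \in \{0, ..., 4\}}. Activity flips on the time scale `tau_a`
#' with rates set by the free-energy difference \eqn{E(m, I)} between the
#' inactive and active state; methylation/demethylation proceed on the much
#' slower time scale \eqn{\tau_m \approx 1/k + 1/l}. The drive parameter
#' `alpha` multiplies the activity-dependent methylation (active, rate
#' \eqn{\alpha k}) and demethylation (inactive, rate \eqn{\alpha l}),
#' encoding the chemical driving by SAM hydrolysis; the network satisfies
#' detailed balance iff \eqn{\alpha = e^{e_0/2k_BT}}, and smaller `alpha`
#' drives it further from equilibrium.
#'
#' @param e0 methylation energy per site (units of `kBT`).
#' @param m0 offset methylation level (dimensionless).
#' @param Ki,Ka ligand dissociation constants of the inactive and active
#'   conformation (concentration units, e.g. uM).
#' @param kBT energy scale (default 1).
#' @param tau_a activity-switching time scale (s).
#' @param k,l base demethylation/methylation rates (1/s).
#' @param alpha nonequilibrium drive parameter, in \eqn{(0, e^{e_0/2k_BT}]}.
#' @return list of class `"sensory_params"`, including the derived
#'   methylation cycle time `tau_m = 1/k + 1/l`.
#' @examples
#' p <- sensory_params()
#' p$tau_m  # 200 s at the default rates
#' @export
sensory_params <- function(e0 = 2, m0 = 1, Ki = 18.2, Ka = 3000, kBT = 1,
                           tau_a = 0.1, k = 0.01, l = 0.01, alpha = 0.5) {
  vals <- c(e0 = e0, m0 = m0, Ki = Ki, Ka = Ka, kBT = kBT,
            tau_a = tau_a, k = k, l = l, alpha = alpha)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all sensory parameters must be positive and finite")
  alpha_eq <- exp(e0 / (2 * kBT))
  if (alpha > alpha_eq * (1 + 1e-12))
    stop(sprintf("alpha must lie in (0, e^{e0/2kBT}] = (0, %.6g]: beyond the equilibrium value the drive reverses sign", alpha_eq))
  structure(list(e0 = e0, m0 = m0, Ki = Ki, Ka = Ka, kBT = kBT,
                 tau_a = tau_a, k = k, l = l, alpha = alpha,
                 tau_m = 1 / k + 1 / l, alpha_eq = alpha_eq),
            class = "sensory_params")
}

#' @export
print.sensory_params <- function(x, ...) {
  cat(sprintf("MCP sensory model: e0 = %.3g kBT, m0 = %.3g, Ki = %.3g, Ka = %.3g\n",
              x$e0, x$m0, x$Ki, x$Ka))
  cat(sprintf("  tau_a = %.3g s, k = %.3g /s, l = %.3g /s (tau_m = %.4g s), alpha = %.4g (equilibrium at %.4g)\n",
              x$tau_a, x$k, x$l, x$tau_m, x$alpha, x$alpha_eq))
  invisible(x)
}

#' Ligand-binding chemical potential
#'
#' \eqn{f(I) = k_BT \log[(1 + I/K_i)/(1 + I/K_a)]}: zero at `I = 0`,
#' increasing in `I`, saturating at \eqn{k_BT \log(K_a/K_i)}.
#'
#' @param I ligand concentration(s), nonnegative.
#' @param p a [sensory_params()] object.
#' @return energy in units of `kBT`.
#' @export
ligand_potential <- function(I, p) {
  stopifnot(inherits(p, "sensory_params"))
  if (any(I < 0)) stop("ligand concentration must be nonnegative")
  p$kBT * log((1 + I / p$Ki) / (1 + I / p$Ka))
}

#' Free-energy difference between inactive and active conformations
#'
#' \eqn{E(m, I) = e_0 (m_0 - m) + f(I)}, linear in the methylation level
#' with slope \eqn{-e_0}: methylation lowers the free energy of the inactive
#' state relative to the active one, ligand binding raises it.
#'
#' @param m methylation level(s) in `0:4`.
#' @param I ligand concentration.
#' @param p a [sensory_params()] object.
#' @return energy in units of `kBT`.
#' @export
free_energy <- function(m, I, p) {
  stopifnot(inherits(p, "sensory_params"))
  if (any(m < 0 | m > 4)) stop("methylation level must be in 0..4")
  p$e0 * (p$m0 - m) + ligand_potential(I, p)
}

# state index: inactive (a=0) m=0..4 -> 1..5, active (a=1) m=0..4 -> 6..10
sensory_index <- function(a, m) 5L * a + m + 1L

#' Build the ten-state sensory-network generator
#'
#' Vertical (activity) transitions between `(0,m)` and `(1,m)` occur at
#' rates \eqn{e^{\mp E(m,I)/2k_BT}/\tau_a} (activation carries the minus
#' sign), so their ratio reproduces the Boltzmann factor of \eqn{E(m, I)}.
#' Horizontal (methylation ladder) transitions: in the active row
#' methylation at \eqn{\alpha k} and demethylation at \eqn{k}; in the
#' inactive row methylation at \eqn{l} and demethylation at \eqn{\alpha l}.
#' The boundary levels have no demethylation at `m = 0` and no methylation
#' at `m = 4`. Every basic four-state cycle has forward/backward
#' rate-product ratio \eqn{e^{e_0/k_BT}/\alpha^2}, hence detailed balance
#' exactly at \eqn{\alpha = e^{e_0/2k_BT}}; this identity is asserted at
#' build time.
#'
#' @param p a [sensory_params()] object.
#' @param I ligand concentration.
#' @return 10x10 `generator` with states labelled `i0..i4` (inactive) and
#'   `a0..a4` (active).
#' @export
build_sensory_Q <- function(p, I) {
  stopifnot(inherits(p, "sensory_params"))
  Q <- matrix(0, 10, 10)
  for (m in 0:4) {
    E <- free_energy(m, I, p)
    Q[sensory_index(0L, m), sensory_index(1L, m)] <- exp(-E / (2 * p$kBT)) / p$tau_a
    Q[sensory_index(1L, m), sensory_index(0L, m)] <- exp(+E / (2 * p$kBT)) / p$tau_a
    if (m < 4) {
      Q[sensory_index(1L, m), sensory_index(1L, m + 1)] <- p$alpha * p$k  # active methylation
      Q[sensory_index(0L, m), sensory_index(0L, m + 1)] <- p$l            # inactive methylation
    }
    if (m > 0) {
      Q[sensory_index(1L, m), sensory_index(1L, m - 1)] <- p$k            # active demethylation
      Q[sensory_index(0L, m), sensory_index(0L, m - 1)] <- p$alpha * p$l  # inactive demethylation
    }
  }
  diag(Q) <- -rowSums(Q)
  # orientation check: every basic cycle ratio must equal e^{e0/kBT}/alpha^2
  m <- 0L
  cyc <- c(sensory_index(0L, m), sensory_index(0L, m + 1L),
           sensory_index(1L, m + 1L), sensory_index(1L, m), sensory_index(0L, m))
  lr <- cycle_log_ratio(Q, cyc)
  stopifnot(abs(lr - (p$e0 / p$kBT - 2 * log(p$alpha))) < 1e-8)
  validate_generator(Q, labels = c(paste0("i", 0:4), paste0("a", 0:4)))
}

#' Observable of the sensory model: total inactive probability
#'
#' @return indicator vector of the five inactive states, so the output is
#'   \eqn{\phi(t) = \sum_m p_{(0,m)}(t)} (one minus the mean activity).
#' @export
sensory_observable <- function() c(rep(1, 5), rep(0, 5))

#' Step response of the sensory network
#'
#' The ligand level steps from `I0` to `I1` at time 0: the initial
#' distribution is the stationary distribution of the `I0` generator, the
#' dynamics follow the `I1` generator, and the output is the total inactive
#' probability.
#'
#' @param p a [sensory_params()] object.
#' @param I0,I1 pre- and post-step ligand concentrations (`I1 > I0`).
#' @return list of class `"sensory_step"` with `response`
#'   (a [spectral_response()]), `metrics` (an `adaptation_metrics`), the
#'   post-step generator `Q1`, and the inputs.
#' @export
step_response <- function(p, I0 = 10 * p$Ki, I1 = 15 * p$Ki) {
  stopifnot(inherits(p, "sensory_params"))
  if (!(I1 > I0)) stop("step_response() requires I1 > I0")
  Q0 <- build_sensory_Q(p, I0)
  Q1 <- build_sensory_Q(p, I1)
  pi0 <- stationary_distribution(Q0)
  resp <- spectral_response(Q1, pi0, sensory_observable())
  metrics <- adaptation_summary(resp, step_protocol(I0, I1))
  structure(list(response = resp, metrics = metrics, Q1 = Q1,
                 params = p, I0 = I0, I1 = I1),
            class = "sensory_step")
}

#' @export
print.sensory_step <- function(x, ...) {
  cat(sprintf("Sensory step response: I %.4g -> %.4g, alpha = %.4g, tau_a = %.3g s\n",
              x$I0, x$I1, x$params$alpha, x$params$tau_a))
  print(x$metrics)
  invisible(x)
}

#' Scan the nonequilibrium drive parameter
#'
#' For each `alpha` on the grid, builds the model, counts the complex
#' eigenvalues of the post-step generator `Q(I1)` (the spectrum that governs
#' the response), computes the step response and its adaptation metrics, and
#' classifies the phase.
#'
#' @param p a [sensory_params()] object; its `alpha` is replaced by each
#'   grid value.
#' @param I0,I1 step protocol concentrations.
#' @param alpha_grid drive values, within \eqn{(0, e^{e_0/2k_BT}]}; default
#'   steps of 0.01 across the full range.
#' @return data frame with columns `alpha`, `n_complex`, `phase`, `phi0`,
#'   `phi_peak`, `t_peak`, `phi_inf`, `gamma`, `epsilon`, `delta`, `eta`.
#' @export
scan_alpha <- function(p, I0 = 10 * p$Ki, I1 = 15 * p$Ki,
                       alpha_grid = seq(0.01, floor(100 * p$alpha_eq) / 100, by = 0.01)) {
  stopifnot(inherits(p, "sensory_params"))
  rows <- lapply(alpha_grid, function(al) {
    pa <- sensory_params(e0 = p$e0, m0 = p$m0, Ki = p$Ki, Ka = p$Ka,
                         kBT = p$kBT, tau_a = p$tau_a, k = p$k, l = p$l,
                         alpha = al)
    st <- step_response(pa, I0, I1)
    m <- st$metrics
    data.frame(alpha = al, n_complex = n_complex_eigenvalues(st$Q1),
               phase = m$phase, phi0 = m$phi0, phi_peak = m$phi_peak,
               t_peak = m$t_peak, phi_inf = m$phi_inf, gamma = m$gamma,
               epsilon = m$epsilon, delta = m$delta, eta = m$eta)
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- p
  out
}

#' Locate a phase boundary on a scanned grid
#'
#' Given an increasing parameter grid and a logical indicator that is TRUE
#' in the low-parameter phase, returns the midpoint of the first grid pair
#' across which the indicator switches off (the boundary is then known to
#' half a grid step).
#'
#' @param grid increasing numeric parameter values.
#' @param in_lower_phase logical, same length.
#' @return boundary estimate, or `NA` if no transition occurs on the grid.
#' @export
locate_phase_boundary <- function(grid, in_lower_phase) {
  stopifnot(length(grid) == length(in_lower_phase))
  n <- length(grid)
  flip <- which(in_lower_phase[-n] & !in_lower_phase[-1])
  if (!length(flip)) return(NA_real_)
  i <- flip[1]
  (grid[i] + grid[i + 1]) / 2
}
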