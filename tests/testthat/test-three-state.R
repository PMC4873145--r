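fig6 <- function(J = 0) three_state_params(c(0.1, 0.5, 0.4),
                                           a = 1.2, b = 0.6, c = 0.2, J = J)
fig6_pi <- c(1, 0, 0)
fig6_g <- c(0, 2, 1)

test_that("flux parametrization builds the stated rates and rejects infeasible flux", {
  Q <- build_three_state_Q(fig6(0))
  expect_equal(unclass(Q)[1, 2], 1.2 / (2 * 0.1), tolerance = 1e-14)  # 6.0
  expect_true(is_detailed_balanced(Q)$balanced)  # J = 0 <=> equilibrium
  expect_error(three_state_params(c(0.1, 0.5, 0.4), 1.2, 0.6, 0.2, J = 0.25),
               "infeasible flux")

  for (seed in 1:30) {
    fx <- random_eq8_Q(seed)
    expect_equal(unname(stationary_distribution(fx$Q)), fx$params$mu,
                 tolerance = 1e-9)
    Jm <- edge_fluxes(fx$Q)
    expect_equal(c(Jm[1, 2], Jm[2, 3], Jm[3, 1]), rep(fx$params$J, 3),
                 tolerance = 1e-12)
  }
})

test_that("parameter recovery round-trips through the builder", {
  p <- params_from_Q(uniform_cycle_Q(3))
  expect_equal(p$mu, rep(1 / 3, 3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(c(p$a, p$b, p$c), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(p$J, 1 / 3, tolerance = 1e-12)

  S <- matrix(c(0, 2, 1, 2, 0, 3, 1, 3, 0), 3, 3)
  Qs <- S; diag(Qs) <- -rowSums(Qs)
  expect_equal(params_from_Q(Qs)$J, 0, tolerance = 1e-14)

  for (seed in 1:100) {
    Q <- random_driven_Q(3, seed = seed)
    Q2 <- build_three_state_Q(params_from_Q(Q))
    expect_equal(unclass(Q2), unclass(Q), tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("oscillation-onset flux: closed form vs discriminant oracle", {
  # uniform case: beta = 0, any positive flux rings
  pu <- three_state_params(rep(1 / 3, 3), 1, 1, 1, 0)
  expect_equal(beta_critical(pu), 0, tolerance = 1e-9)
  expect_gt(n_complex_eigenvalues(build_three_state_Q(
    three_state_params(rep(1 / 3, 3), 1, 1, 1, 0.05))), 0)

  # the reference fixture: beta ~ 0.917 (beyond its feasibility bound 0.2)
  b6 <- beta_critical(fig6())
  expect_equal(b6, sqrt(0.8408), tolerance = 1e-12)
  expect_equal(b6, oracle_beta(c(0.1, 0.5, 0.4), 1.2, 0.6, 0.2), tolerance = 1e-8)

  set.seed(1)
  for (i in 1:60) {
    fx <- random_eq8_Q(2000 + i)
    p <- fx$params
    bc <- beta_critical(p)
    expect_equal(bc, oracle_beta(p$mu, p$a, p$b, p$c), tolerance = 1e-8)
    # complex eigenvalues appear exactly above beta (when feasible)
    Jmax <- min(p$a, p$b, p$c)
    if (bc > 1e-5 && bc < Jmax - 1e-5) {
      plo <- three_state_params(p$mu, p$a, p$b, p$c, bc - 1e-6)
      phi_ <- three_state_params(p$mu, p$a, p$b, p$c, bc + 1e-6)
      expect_identical(n_complex_eigenvalues(build_three_state_Q(plo)), 0L)
      expect_identical(n_complex_eigenvalues(build_three_state_Q(phi_)), 2L)
    }
    # equilibrium always has a real spectrum
    p0 <- three_state_params(p$mu, p$a, p$b, p$c, 0)
    expect_identical(n_complex_eigenvalues(build_three_state_Q(p0)), 0L)
  }
})

test_that("transient indicators and the simple-overshoot criterion", {
  # starting at stationarity: E = 0, F = 0
  p <- fig6(0.1)
  ti <- transient_indicators(p, p$mu, fig6_g)
  expect_equal(ti$E, 0, tolerance = 1e-10)
  expect_equal(ti$F, 0, tolerance = 1e-12)

  # E increases with J on the reference fixture
  E0 <- transient_indicators(fig6(0), fig6_pi, fig6_g)$E
  E2 <- transient_indicators(fig6(0.2), fig6_pi, fig6_g)$E
  expect_gt(E2, E0)

  # complex regime is rejected
  posc <- three_state_params(c(0.2, 0.3, 0.5), 1, 1, 1, 0.9)
  expect_error(transient_indicators(posc, c(1, 0, 0), fig6_g), "complex regime")

  # monotone structure in the driving orientation: E increasing,
  # -lambda2 F decreasing in J
  set.seed(2)
  for (i in 1:25) {
    fx <- random_eq8_Q(3000 + i)
    o <- orient_flux_direction(fx$params, random_simplex(3), stats::runif(3))
    p <- o$params
    Jup <- min(beta_critical(p), min(p$a, p$b, p$c)) * 0.999
    if (Jup <= 0) next
    Js <- seq(0, Jup, length.out = 9)
    ind <- lapply(Js, function(J) transient_indicators(
      three_state_params(p$mu, p$a, p$b, p$c, J), o$pi0, o$g))
    E <- vapply(ind, `[[`, numeric(1), "E")
    mLF <- vapply(ind, function(x) -x$lambda2 * x$F, numeric(1))
    expect_true(all(diff(E) > -1e-10 * max(1, abs(E))))
    if (ind[[1]]$F > 1e-8) expect_true(all(diff(mLF) < 1e-8 * max(1, abs(mLF))))
  }
  # the orientation helper itself: reversing the cycle negates the slope
  o1 <- orient_flux_direction(fig6(0.1), fig6_pi, fig6_g)
  expect_gte(o1$dE_dJ, 0)
  expect_equal(abs(o1$params$J), 0.1)
})

test_that("criterion sign matches the phase label below the oscillation onset", {
  set.seed(3)
  checked <- 0
  for (i in 1:80) {
    fx <- random_eq8_Q(5000 + i)
    p <- fx$params
    Jup <- min(beta_critical(p), min(p$a, p$b, p$c))
    if (Jup <= 1e-4) next
    pi0 <- random_simplex(3)
    g <- stats::runif(3)
    J <- stats::runif(1, 0, Jup * 0.999)
    pj <- three_state_params(p$mu, p$a, p$b, p$c, J)
    ti <- transient_indicators(pj, pi0, g)
    pre <- check_response_preconditions(
      spectral_response(build_three_state_Q(pj), pi0, g))
    # the criterion characterizes overshoot under the standard preconditions
    if (!(pre$slope0_positive && pre$steady_ge_initial)) next
    scale <- abs(ti$E) + abs(ti$lambda2 * ti$F)
    if (abs(ti$criterion) < 1e-6 * max(scale, 1e-12)) next  # marginal
    phase <- classify_phase(spectral_response(build_three_state_Q(pj), pi0, g))
    expect_identical(phase, if (ti$criterion > 0) "SIMPLE" else "NON")
    checked <- checked + 1
  }
  expect_gt(checked, 15)
})

test_that("overshoot-onset flux: root bracketing and degenerate outcomes", {
  # equilibrium overshoot exists on the reference fixture => critical flux 0
  af <- alpha_flux_critical(fig6(), fig6_pi, fig6_g)
  expect_identical(af$status, "at_zero")
  expect_identical(af$value, 0)
  expect_identical(classify_phase(spectral_response(build_three_state_Q(fig6(0)),
                                                    fig6_pi, fig6_g)), "SIMPLE")

  # starting at stationarity: flat response, the onset is never reached
  afmu <- alpha_flux_critical(fig6(), fig6(0)$mu, fig6_g)
  expect_identical(afmu$status, "not_reached")

  # when a genuine root exists, the phase flips across it
  set.seed(4)
  found <- 0
  for (i in 1:120) {
    fx <- random_eq8_Q(6000 + i)
    p <- fx$params
    pi0 <- random_simplex(3)
    g <- stats::runif(3)
    af <- alpha_flux_critical(p, pi0, g)
    if (af$status != "root") next
    eps <- 0.05 * min(af$beta, af$J_max)
    if (af$value < eps || af$value > min(af$beta, af$J_max) - eps) next
    lo <- three_state_params(p$mu, p$a, p$b, p$c, af$value - eps)
    hi <- three_state_params(p$mu, p$a, p$b, p$c, af$value + eps)
    pre <- check_response_preconditions(
      spectral_response(build_three_state_Q(hi), pi0, g))
    if (!(pre$slope0_positive && pre$steady_ge_initial)) next
    expect_identical(classify_phase(spectral_response(build_three_state_Q(lo), pi0, g)), "NON")
    expect_identical(classify_phase(spectral_response(build_three_state_Q(hi), pi0, g)), "SIMPLE")
    found <- found + 1
    if (found >= 8) break
  }
  expect_gt(found, 2)
})

test_that("flux sweep on the reference fixture: efficiency rises, endpoints fixed", {
  sw <- sweep_flux(fig6(), fig6_pi, fig6_g, seq(0, 0.2, by = 0.02))
  expect_true(all(diff(sw$eta) > 0))                       # strictly increasing
  expect_true(all(diff(sw$phi_peak) > 0))
  expect_equal(sw$phi0, rep(sw$phi0[1], nrow(sw)), tolerance = 1e-12)
  expect_equal(sw$phi_inf, rep(sw$phi_inf[1], nrow(sw)), tolerance = 1e-10)
  expect_true(all(sw$phase == "SIMPLE"))

  # fast-state variant: peak output near-linear in J (residual < 1% of range)
  pf <- three_state_params(c(1e-4, 0.5, 0.4999), 1.2, 0.6, 0.2, 0)
  swf <- sweep_flux(pf, fig6_pi, fig6_g, seq(0.02, 0.2, by = 0.02))
  fit <- stats::lm(phi_peak ~ J, data = swf)
  expect_lt(max(abs(stats::resid(fit))), 0.01 * diff(range(swf$phi_peak)))
})

test_that("fast-state elimination tracks the full dynamics", {
  # reference fast fixture: state 1 holds 1e-4 of the stationary mass
  pf <- three_state_params(c(1e-4, 0.5, 0.4999), 1.2, 0.6, 0.2, 0.1)
  Q <- build_three_state_Q(pf)
  red <- fast_state_reduction(Q, fig6_pi, fig6_g, fast_state = 1)
  expect_gt(red$ratio, 100)
  r_full <- spectral_response(Q, fig6_pi, fig6_g)
  ts <- default_time_grid(r_full, 80)
  full <- predict(r_full, ts)
  approx <- predict(red, ts)
  # compare after the fast boundary layer has relaxed
  late <- ts > 5 / abs(Re(r_full$eigenvalues[which.max(abs(Re(r_full$eigenvalues)))]))
  expect_lt(max(abs(full[late] - approx[late])) / diff(range(full)), 0.005)

  # peak output of the reduced model within 2% of the full model (the
  # overshoot peak sits at the end of the fast boundary layer, which the
  # reduced model carries as its initial condition)
  pk_full <- find_peak(r_full)
  pk_red <- max(predict(red, c(0, exp(seq(log(1e-3), log(60), length.out = 3000)))))
  expect_lt(abs(pk_full$phi_peak - pk_red) / pk_full$phi_peak, 0.02)

  # a leisurely "fast" state triggers the accuracy warning
  expect_warning(fast_state_reduction(build_three_state_Q(fig6(0)),
                                      fig6_pi, fig6_g, 1, min_ratio = 100),
                 "time-scale ratio")
})

test_that("phase sequence along increasing flux is monotone NON -> SIMPLE -> OSCILLATORY", {
  rank <- c(NON = 1, SIMPLE = 2, OSCILLATORY = 3)
  set.seed(5)
  for (i in 1:40) {
    fx <- random_eq8_Q(8000 + i)
    o <- orient_flux_direction(fx$params, random_simplex(3), stats::runif(3))
    p <- o$params
    Js <- seq(0, min(p$a, p$b, p$c) * 0.999, length.out = 12)
    ph <- vapply(Js, function(J) classify_phase(spectral_response(
      build_three_state_Q(three_state_params(p$mu, p$a, p$b, p$c, J)),
      o$pi0, o$g)), character(1))
    expect_true(all(diff(rank[ph]) >= 0))
  }
})
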