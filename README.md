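# ctmcadapt

Overshoot and adaptation analysis for finite-state Markov jump models of
biochemical sensory systems.

Many sensory systems — bacterial chemoreceptors, ion channels, hormone
receptors — respond to a step increase of their input with a transient rise
to a peak followed by recovery toward a plateau. `ctmcadapt` provides the
linear-algebraic machinery to analyse this behaviour exactly in
continuous-time Markov chain (CTMC) models, and to connect it to how far the
system is driven from thermodynamic equilibrium.

## The model

A biochemical system with `N` states evolves under the master equation
`dp/dt = p Q`, where `Q` is the generator matrix (off-diagonal transition
rates, rows summing to zero). For an observable `g`, the output

```
phi(t) = p(t) g' = phi_inf + sum_{i=1}^{N-1} c_i exp(lambda_i t)
```

expands over the nonzero eigenvalues of `Q` (all with negative real part).
The package computes this decomposition, classifies the step response as

* **NON** — monotone output, no overshoot;
* **SIMPLE** — a single peak exceeding both the initial and the steady
  output, carried by real relaxation modes;
* **OSCILLATORY** — overshoot carried by conjugate complex modes,
  i.e. a damped cosine `2|c| exp(-lambda t) cos(omega t + phase)`;

and scores adaptation by the sensitivity `gamma`, error `epsilon`, accuracy
`delta = 1/epsilon`, and the input-independent efficiency

```
eta = 1 - epsilon/gamma = (phi_peak - phi_inf) / (phi_peak - phi_0)  in [0, 1].
```

Three exact results organise the analysis:

* **Equilibrium generators have real spectra** (detailed balance makes
  `diag(sqrt(mu)) Q diag(1/sqrt(mu))` symmetric), so oscillatory overshoot
  requires nonequilibrium driving.
* **The Dmitriev–Dynkin–Karpelevich bound**: every complex eigenvalue pair
  `-lambda ± i omega` of an `N`-state generator satisfies
  `lambda/|omega| >= tan(pi/N)`, with equality only for the uniform
  unidirectional cycle — which is why ringing is hard to see in small
  networks.
* **Three-state flux parametrization**: any irreducible 3-state generator is
  determined by its stationary distribution `mu`, edge flow sums `a, b, c`
  and the net cycle flux `J` (`J = 0` iff equilibrium). The spectrum turns
  complex exactly at a critical flux `beta` (closed form implemented and
  cross-checked against the characteristic-polynomial discriminant), and
  below `beta` the response overshoots iff `E + lambda_2 F > 0` with
  `E = phi'(0)`, `F = phi_inf - phi_0`. Along increasing flux the phase can
  only move NON → SIMPLE → OSCILLATORY.

The package also ships the ten-state methylation/activity model of the
*E. coli* MCP chemotaxis receptor (activity `a ∈ {0,1}`, methylation
`m ∈ 0..4`), where a drive parameter `alpha` sets the strength of the
chemical driving by SAM hydrolysis: detailed balance holds exactly at
`alpha = exp(e0/2)`, and lowering `alpha` pushes the receptor through the
non-adaptation → simple → oscillatory sequence.

## Worked example

A ligand step from `10 Ki` to `15 Ki` on the chemotaxis receptor with
moderate drive (`alpha = 0.5`) and fast activity switching:

```r
library(ctmcadapt)

p  <- sensory_params(alpha = 0.5, tau_a = 0.1)   # e0 = 2, Ki = 18.2 uM, ...
st <- step_response(p)                           # I: 10 Ki -> 15 Ki
st
#> Sensory step response: I 182 -> 273, alpha = 0.5, tau_a = 0.1 s
#> Adaptation metrics
#>   phi0 = 0.515282, phi_peak = 0.558028 (t = 0.39488), phi_inf = 0.531224
#>   gamma = 0.165913, epsilon = 0.0618751, delta = 16.1616, eta = 0.627063
#>   phase: SIMPLE
```

The inactive probability jumps from 0.515 to a peak of 0.558 about 0.4 s
after the step, then relaxes back to 0.531: the receptor adapts, recovering
63% of its excursion (`eta = 0.627`). Driving the system harder
(smaller `alpha`) raises the peak and pushes `eta` toward 1; at the
equilibrium drive `alpha = exp(1)` the response is monotone and no
adaptation occurs.

The same machinery applies to any generator:

```r
Q <- validate_generator(rbind(c(-1, 1), c(2, -2)))
r <- spectral_response(Q, pi0 = c(1, 0), g = c(0, 1))
r$phi_inf          # 1/3
coef(r)            # eigenvalue -3, coefficient -1/3
plot(r)            # phi(t) on a log-time axis
```

A command-line front end (`inst/cli/ctmcadapt.R`) exposes `respond`,
`scan-alpha`, `sweep-flux`, `fixtures` and `diagnose` subcommands over the
same functions.

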