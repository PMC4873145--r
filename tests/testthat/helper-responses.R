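# Assemble a spectral_response object directly from modes, for closed-form
# test cases where no generator is needed.
make_response <- function(eigenvalues, coefficients, phi_inf,
                          g = c(0, 1), n_states = length(eigenvalues) + 1) {
  lam <- as.complex(eigenvalues)
  cs <- as.complex(coefficients)
  cx <- abs(Im(lam)) > 1e-9 * pmax(1, abs(lam))
  structure(list(
    Q = NULL, pi0 = NULL, g = g, mu = NULL,
    phi0 = phi_inf + sum(Re(cs)), phi_inf = phi_inf, n_states = n_states,
    mode = "spectral", eigenvalues = lam, coefficients = cs,
    modes = data.frame(re = Re(lam), im = Im(lam), decay = -Re(lam),
                       omega = abs(Im(lam)),
                       amplitude = ifelse(cx, 2 * Mod(cs), Re(cs)),
                       phase = ifelse(cx, Arg(cs), 0), complex = cx)),
    class = "spectral_response")
}

# conjugate-pair response phi(t) = phi_inf + A e^{-decay t} cos(omega t + phase)
make_damped_cosine <- function(decay, omega, A, phase, phi_inf) {
  c1 <- (A / 2) * exp(1i * phase)
  make_response(c(complex(real = -decay, imaginary = omega),
                  complex(real = -decay, imaginary = -omega)),
                c(c1, Conj(c1)), phi_inf, n_states = 3)
}
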