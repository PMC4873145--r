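Package: ctmcadapt
Title: Overshoot and Adaptation Analysis for Finite-State Markov Jump Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spectral analysis of transient responses in continuous-time Markov
    chains modelling biochemical sensory systems. Decomposes the output of a
    master equation into exponential relaxation modes, classifies step
    responses into non-adaptation, simple adaptation and oscillatory
    adaptation, and computes adaptation performance metrics (sensitivity,
    error, accuracy, efficiency). Includes the exact three-state
    parametrization by stationary distribution and net cycle flux with its
    critical flux values for the onset of overshoot and of damped
    oscillations, the Dmitriev-Dynkin-Karpelevich bound on complex
    eigenvalues, quasi-steady-state elimination of fast states, and the
    ten-state methylation/activity model of the E. coli chemotaxis receptor
    with scans over the strength of the nonequilibrium drive.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
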