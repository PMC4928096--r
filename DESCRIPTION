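Package: heartpp
Title: Inhomogeneous Point-Process Analysis of Heartbeat Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Instantaneous analysis of heartbeat dynamics through
    inhomogeneous inverse-Gaussian point-process models. The conditional
    mean of the next R-R interval is parametrized as a nonlinear
    autoregressive model with Laguerre expansion of the Wiener-Volterra
    kernels, fitted by local maximum likelihood on a fine time grid.
    From the fitted model the package derives instantaneous time-domain
    moments, spectra and band powers, bispectra and their band integrals,
    dominant Lyapunov exponents, and inhomogeneous point-process
    approximate and sample entropy, together with time-rescaling
    goodness-of-fit, stimulus-locked feature extraction, and SVM-based
    classification with recursive feature elimination. A synthetic
    generator simulates event series and full stimulation protocols from
    the same model family so the whole chain can be exercised without
    recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
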