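Package: robustavg
Title: Robust Averaging Models of Perceptual Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-fitting toolkit for studying nonlinear
    ("robust") averaging in perceptual categorisation. Generates synthetic
    orientation-averaging sessions (eight-grating arrays judged clockwise or
    counter-clockwise of a central reference), implements a family of decision
    models built on a sign-preserving power-law transducer with late
    (post-integration) logistic noise, together with equivalent-gain linear,
    early-noise and population-coding variants, fits them by exhaustive
    maximum-likelihood grid search, estimates binned probit decision-weight
    profiles (psychophysical kernels), and maps simulated accuracy over the
    transducer-exponent by late-noise plane to show when compressive
    transduction protects choices from noise arising during neural
    integration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
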