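Package: pushupkin
Title: Force-Platform Kinetics of the Plyometric Push-Up
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes whole-body force, velocity and power during plyometric
    push-ups from hands and feet force-platform recordings. Implements both the
    two-platform method (summing measured hands and feet ground reaction
    forces) and the one-platform method (assuming a constant feet force equal
    to its static value), with Butterworth low-pass filtering, threshold-based
    phase detection, impulse-momentum velocity estimation by trapezoidal
    integration, and extraction of eight body-weight-normalized outcome
    variables. Includes a mechanistic synthetic push-up generator with analytic
    ground truth and the method-comparison statistical layer (paired and
    independent t-tests, Cohen's d with interpretation bands, correlations
    with strength bands, and simple linear regression between methods).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
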