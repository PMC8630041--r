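Package: rlci
Title: Response-Locked Classification Images for Dynamic Contrast Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for response-locked reverse
    correlation in dynamic detection tasks. Generates one-dimensional
    dynamic-noise stimuli with ramping luminance targets, simulates a model
    observer built from a space-time separable contrast filter (difference of
    Gaussians by biphasic impulse response) feeding a leaky evidence
    accumulator with decision bounds, computes response-locked classification
    images, impact curves, reaction-time-split kernels and variance kernels
    from trial logs, and estimates model parameters by simulation-based
    derivative-free optimization with common random numbers, including a
    parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
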