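Package: oscwave
Title: Traveling Waves in Forced Chains of Pulse-Coupled Phase Oscillators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.net", role = c("aut", "cre"))
Description: Exact event-driven simulation and analysis of semi-infinite
    unidirectional chains of piecewise-affine type-I phase oscillators under
    periodic forcing. Provides the closed-form construction of case-(a)
    traveling-wave shapes, the admissibility intervals of the phase shift
    (existence, stability, and uniform-forcing robustness), the stroboscopic
    period return map with its piecewise-affine decomposition, fixed points
    and rotation number, and end-to-end wave-generation experiments with
    convergence diagnostics. An exact-rational arithmetic mode is available
    for closed-form fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
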