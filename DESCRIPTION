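Package: fibrocontrol
Title: Spectral Galerkin Simulation and Optimal Drug Scheduling for a
    Homogenized Model of Pulmonary Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates myofibroblast density in injured lung tissue with a
    homogenized reaction-diffusion model and computes optimal time-varying
    anti-TGF-beta and anti-PDGF dosing schedules. The parabolic model is
    semi-discretized in space with a Legendre-Gauss-Lobatto spectral Galerkin
    method (one or two dimensions, tensor-product elements), yielding a linear
    state-space system with constant activation source. The dosing problem is
    posed as a linear-quadratic regulator with affine dynamics and solved by a
    backward extended Riccati sweep (scalar and full-matrix modes) with linear
    feedback synthesis, following Pontryagin's minimum principle. Includes
    forward Euler integration with analytic closed-form oracles, dose-response
    and convergence studies, and machine-readable study reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
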