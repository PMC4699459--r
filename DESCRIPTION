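Package: parabead
Title: Deterministic Diffusion-Ratchet Simulation of the In Vitro ParA-ParB System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the directed motion of a ParB-coated bead over a
    DNA-bound ParA surface as a deterministic reaction-advection system: a
    gridded surface ParA concentration is depleted by a Gaussian removal
    kernel centred on the bead while the bead moves, overdamped, under the
    chemotactic force integral of the remaining ParA. Includes ParA
    rebinding from a well-mixed buffer (with optional cooperativity), ParA
    surface diffusion, a two-dimensional extension, the analytic
    traveling-wave steady-state speed theory with self-consistent speed,
    optimal-kernel-ratio and 1D/2D crossover finders, and trajectory
    post-processing (lag/speed fitting, acceleration-law and stall-boundary
    fits, parameter sweeps). A thin command-line interface drives
    reproducible, seeded runs from flat config files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
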