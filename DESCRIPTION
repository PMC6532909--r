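Package: pillarforce
Title: Forces Exerted by Growing Spheroids from 3D Micropillar Deflection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures the forces that growing multicellular spheroids exert on
    rings of high-aspect-ratio elastic PDMS micropillars. Reconstructs 3D
    pillar deflection profiles from confocal z-stacks by slice-wise
    segmentation and tracking, models pillar bending as a clamped
    Euler-Bernoulli cantilever under a partially distributed horizontal load
    (closed form plus a 1D finite-element beam with optional Timoshenko shear
    correction), and inverts deflection profiles to forces by sweeping
    candidate loads against a precomputed abacus of simulated curves scored
    with sum-of-squares, R-squared and largest-shift statistics. Ships a
    synthetic confocal stack renderer with ground truth so the entire chain
    is testable end to end without experimental data, and device-level
    reporting tools (force summaries by pillar stiffness, temporal force
    rates, two-sample comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
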