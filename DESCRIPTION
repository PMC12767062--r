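Package: ecsrheomap
Title: Extracellular-Space Rheology Mapping from Single-Particle Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of brain extracellular-space (ECS) rheology
    in and around amyloid plaques from single-particle tracking data.
    Implements sub-pixel super-localization of quantum-dot movies, optimal
    frame-to-frame trajectory linking, mean-squared-displacement (MSD)
    rheology (instantaneous diffusion coefficients, confinement areas,
    mobility fractions, paired relative-change statistics), concentric
    plaque-ROI penetrability analysis, plaque circularity phenotyping,
    local ECS width estimation from elongated-probe (nanotube) trajectories,
    and extracellular-matrix mask metrics (percent area, skeletonization,
    box-counting fractal dimension). A synthetic-data generator simulates
    plaque geometries, confined Brownian motion and rendered movies with
    known ground truth so every stage of the pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml,
    tiff,
    nortest,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
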