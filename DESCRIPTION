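Package: sh2spt
Title: Single-Molecule SH2 Membrane Recruitment Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of time-resolved SH2-domain membrane
    recruitment measured by single-particle tracking (sptPALM/TIRF). Provides a
    stochastic simulator of phosphotyrosine site creation, progressive site
    clustering and SH2 binding with local rebinding; rendering of synthetic
    movies with realistic camera noise; single-molecule localization,
    nearest-neighbor tracking and MSD-based diffusion estimation; apparent
    on-rate (gamma_on) and dwell-time based apparent off-rate (lambda_off)
    estimators with photobleaching correction; first-order exponential recovery
    fitting; k-means intensity thresholding for binding-site cluster
    segmentation and cluster/non-cluster trajectory partitioning; the membrane
    occupancy kinetic ODE with numeric and analytic (integrating factor)
    solutions and diffusion-limited on-rate estimates; and far-Western band
    table analytics (per-probe normalization, relative specificity,
    average-linkage hierarchical clustering with uncentered correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    deSolve,
    minpack.lm,
    EBImage,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
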