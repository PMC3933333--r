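Package: stereoPC
Title: Design-Based Stereology Simulation for Cerebellar Purkinje Cell Density
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Virtual-tissue simulation and estimation toolkit for design-based
    stereology of the cerebellar Purkinje cell (PC) monolayer. Generates 3D
    phantoms of cerebellar regions with PC somata placed on convoluted folium
    surfaces at known ground-truth density, virtually sections them, applies
    optical-disector counting with unbiased counting frames under systematic
    uniform random sampling, and estimates PC density with Gundersen (m = 1)
    coefficients of error and Cavalieri regional volumes. Includes a calibrated
    postmortem cohort simulator (demographics, regional density effects, ADI-R
    eye-contact item) and the matching statistical battery: Levene-gated
    t-tests, volume-weighted mixed-model ANOVA, Benjamini-Hochberg FDR,
    bootstrap Spearman correlations, and noncentral-F observed power.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr,
    lme4,
    lmerTest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
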