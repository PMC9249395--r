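Package: cuspkit
Title: Tooth-Cusp Morphogenesis Simulation and Landmark-Based Shape Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cusp patterning in shark teeth. Provides an
    activator-inhibitor reaction-diffusion simulator of tooth morphogenesis on
    a growing epithelial strip with cusp detection and phenotype classification,
    a parameter-sweep engine for in silico perturbation experiments, TPS
    landmark input/output with sliding semilandmark curve definitions,
    generalized Procrustes superimposition with bending-energy or
    Procrustes-distance semilandmark sliding, and shape statistics: Procrustes
    ANOVA with residual randomization permutation (RRPP), principal component
    analysis of shape, centroid-size models with Tukey contrasts, variance
    F-tests and proportion chi-square tests. A hierarchical synthetic landmark
    data generator emulates a three-treatment Wnt-perturbation study design so
    the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
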