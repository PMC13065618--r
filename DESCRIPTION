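Package: leukoflow
Title: Hydrodynamic Profiling of Leukocyte-Endothelium Interactions in Flow Chambers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying leukocyte behaviour in parallel-plate
    flow-chamber video assays. Reads per-cell trajectory exports, derives
    frame-to-frame velocity and acceleration series, and computes both the
    classical interaction parameters (rolling velocity, rolling flux, firm
    adhesion) and an extended panel of 45 hydrodynamic descriptors covering
    velocity and acceleration distributions, rolling-event balance,
    population heterogeneity, range-interaction products, and per-range cell
    counts. Includes group statistics (one-way ANOVA with Tukey HSD,
    Pearson/Spearman correlation matrices), an SPSS-style stepwise linear
    discriminant analysis with Wilks' lambda selection, leave-one-out
    validation, variance inflation factors and varimax-rotated principal
    components, and a seeded stochastic simulator of flow-chamber cohorts
    (free flow, rolling, arrest, jerk events) for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
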