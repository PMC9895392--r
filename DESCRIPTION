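Package: metagdf15
Title: Meta-Analysis of GDF-15 Expression in Gestational Diabetes
Version: 1.0.0
Authors@R:
    person("metagdf15", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Random-effects meta-analysis toolkit built around the combined
    analysis of growth differentiation factor 15 (GDF-15) expression in
    gestational diabetes mellitus (GDM). Provides median/quartile to
    mean/SD summary conversion (Wan and Luo estimators), standardized mean
    differences (Cohen's d, Hedges' g) with analytic variances,
    fixed-effect and DerSimonian-Laird random-effects pooling with
    heterogeneity statistics, Begg rank-correlation and Egger regression
    publication-bias tests, leave-one-out and criteria-restricted
    sensitivity analyses, a synthetic-study generator for end-to-end
    validation, and a command-line interface. Ships the study-level
    summary data of the GDF-15/GDM analysis as packaged fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
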