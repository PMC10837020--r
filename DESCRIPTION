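Package: photothermal
Title: Photosynthetic Heat Tolerance Analysis for Wheat Gas-Exchange,
    Fluorescence and Metabolite Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying photosynthetic acclimation to night
    warming in wheat. Fits the Farquhar-von Caemmerer-Berry (FvCB) C3
    photosynthesis model to A-Ci curves with mesophyll conductance
    coupling, models temperature responses of photosynthetic capacity
    (peaked Arrhenius with deactivation, and quadratic fits) with optimum
    temperature extraction, estimates the critical temperature of PSII
    (Tcrit) from chlorophyll fluorescence temperature ramps by two-line
    breakpoint regression, runs comparative-regression model selection and
    ANOVA with post-hoc letters, and normalizes GC-MS metabolite abundance
    tables for PCA and permutation-based multivariate ANOVA (PERMANOVA).
    Includes synthetic-data generators with known ground truth for every
    input the pipeline consumes, so the full analysis chain is testable
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
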