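Package: projectome
Title: Quantitative Analysis of Brain-Wide Retrograde-Tracing Projectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the areal and laminar organization of
    cortical input mapped with retrograde tracers. Converts per-animal
    (hemisphere, area, layer) nucleus counts into normalized projection
    weights (hemisphere shares, areal and modular fractional counts,
    laminar profiles), computes the fraction of infragranular labeled
    neurons (fILN) as an anatomical hierarchy statistic with
    layer-ablation variants, classifies laminar dominance, and compares
    hierarchy across hemispheres and cortical modules. Ships the
    exclusion and quality-control filters used for cellfinder-style count
    tables, the statistical comparison machinery (normality-screened test
    routing, Bonferroni and Tukey-Kramer corrections, per-animal
    correlations), and a Dirichlet-multinomial cohort simulator with an
    explicit ground truth so every pipeline stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    jsonlite,
    yaml,
    nortest,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
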