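Package: fermdoe
Title: Design of Experiments and Response-Surface Optimization for
    Fermentation Media
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for statistical optimization of microbial enzyme
    production: Plackett-Burman two-level screening designs with
    main-effect estimation and Lenth significance analysis, rotatable
    central composite designs, second-order response-surface fitting
    with full ANOVA (including the lack-of-fit versus pure-error
    split), model diagnostics (PRESS, predicted R-squared, coefficient
    of variation), stationary-point and constrained box optimization,
    enzyme-activity unit arithmetic (nanokatal, Beer-Lambert assay
    conversion), and pulp biobleaching metrics (kappa-number reduction,
    ISO brightness increase). Includes seeded synthetic-data generators
    with known ground truth for every analysis stage, and a bundled
    worked study of laccase production optimization in bacterial
    submerged fermentation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
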