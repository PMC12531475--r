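Package: agreebin
Title: Agreement Analysis for Binary Ratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inter- and intra-observer agreement studies with a
    binary outcome (e.g., normal/abnormal test results). Computes the
    proportion of agreement, specific positive and negative agreement
    (Dice/F1 and its Jaccard transform), chance-corrected coefficients
    under three definitions of chance (G-index/PABAK, Cohen/Conger,
    Scott/Fleiss), Krippendorff's alpha and Gwet's AC1, for two or more
    observers with possibly unequal numbers of ratings per patient.
    Provides delta-method (influence-function) standard errors, Wald,
    continuity-corrected, bootstrap and Fisher-z confidence intervals,
    sample-size calculators for precision (confidence-interval width) and
    power-based planning, and simulators of rating matrices with known
    prevalence and intraclass correlation. Includes a worked
    cardiotocography (CTG) example with five observers and twenty
    patients reconstructed from its published summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
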