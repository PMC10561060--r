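Package: tpmadapt
Title: Tethered-Particle-Motion Models of Chemotactic Adaptation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative models of methylation-dependent adaptation in
    bacterial chemotaxis. Implements the Monod-Wyman-Changeux (MWC) model of
    receptor-cluster kinase activity and its inversion from activity to
    methylation level, adaptation kinetics with linear and cubic
    demethylation variants, receptor tether geometry for the Tar and Tsr
    chemoreceptors, the translated-Gaussian tethered-particle-motion (TPM)
    model of the methyltransferase CheR and its fit to steady-state activity
    ratios, a closed-form stationary analysis of sequential multisite
    methylation under site-dependent enzyme encounter probabilities, and a
    processing pipeline for FRET-style kinase-activity traces. A synthetic
    experiment generator with recorded ground truth makes every stage of the
    analysis testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
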