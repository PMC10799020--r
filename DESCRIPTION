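Package: patchfrap
Title: Patch/FRAP Analysis of Membrane Receptor Complex Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling, simulation and fitting of fluorescence
    recovery after photobleaching (FRAP) with a Gaussian laser spot, and the
    patch/FRAP inference layer that converts condition-wise changes in the
    mobile fraction (R_f) and lateral diffusion coefficient (D) of a
    membrane receptor into stable-complex fractions and stable/transient
    interaction calls. Includes a closed-form lateral-diffusion recovery
    model with an immobile subpopulation, a noisy-curve and cohort
    generator, a reaction-diffusion Monte Carlo simulator of receptors
    binding to immobilized antibody-crosslinked patches, bounded nonlinear
    least-squares curve fitting with half-time initialization and
    recovery-percentage quality control, and group statistics (one-way
    ANOVA with Bonferroni post-hoc contrasts, Student's t test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
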