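Package: thermodsc
Title: Model-Free and Model-Based Analysis of Protein Unfolding DSC Thermograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts differential scanning calorimetry (DSC) excess heat
    capacity thermograms of protein unfolding into model-free thermodynamic
    profiles (enthalpy, entropy and Gibbs free energy as functions of
    temperature) and fits and compares four unfolding models: the standard
    chemical-equilibrium two-state model, its extent-of-unfolding-weighted
    variant, a statistical-mechanical two-state model, and the multistate
    cooperative Zimm-Bragg model. Produces protein stability reports (melting
    and cold-denaturation temperatures, transition widths, enthalpy
    decomposition, cooperativity and nucleation free energy) and includes a
    seeded synthetic-thermogram generator for heating scans, exothermic
    cooling scans and double cold-plus-heat transitions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
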