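Package: memtug
Title: One-Dimensional Elastic Model of Gramicidin Dimer Dissociation in
    Lipid Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the dissociation of the membrane-spanning gramicidin A
    dimer as motion on a one-dimensional potential energy surface: a Morse
    subunit-subunit bond coupled to a harmonic bilayer deformation term that
    penalizes hydrophobic mismatch between the channel and the host bilayer.
    Locates and classifies the stationary points of the resulting landscape
    (conducting-dimer well, transition state, dissociated well), derives
    Arrhenius dissociation rates, mean channel lifetimes and the membrane
    disjoining force, and sweeps bilayer thickness and bilayer stiffness to
    recover the approximately linear lifetime trends observed in
    single-channel experiments. Tidy interfaces throughout: scans return
    tibbles, fitted landscapes have tidy(), glance() and autoplot() methods,
    and a thin command-line wrapper is included for shell use.
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
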