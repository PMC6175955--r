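Package: hdxshift
Title: Differential Hydrogen-Deuterium Exchange Analysis of Conformational
    Equilibria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Peptide-level differential hydrogen-deuterium exchange mass
    spectrometry (HDX-MS) analysis for detecting shifts in protein
    conformational equilibria, with an emphasis on membrane transporters.
    Implements relative fractional uptake, per-timepoint and summed
    delta-HDX between two states, a Houde-style pooled-variance global
    significance threshold combined with a two-sided unpaired t-test,
    peptide-to-residue consolidation with binary-color structural mapping
    onto PDB B-factors, and Woods-plot data export. Includes a two-state
    (outward-facing/inward-facing) Linderstrom-Lang exchange-kinetics
    simulator with per-residue protection factors and in-silico digestion
    for end-to-end validation, and a trajectory gate-distance module
    (center-of-mass distance between Calpha residue groups, time traces,
    trailing-window distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    graphics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
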