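Package: plasmadose
Title: Equivalent-Circuit Dose Modelling of Discharge-Plasma Cell Death
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the electrical dose delivered to a confluent cell layer in a
    96-well plate during microdischarge plasma treatment. The well contents
    (buffer, cell layer with membranes, dish bottom) are discretized into 40
    concentric annuli and represented as an RC ladder network with radial
    links; the network is solved in sinusoidal steady state by complex nodal
    analysis (with a brute-force transient integrator as an independent
    cross-check) to obtain the cytoplasm current density, instantaneous power
    density, and injected energy density at every radius. Two threshold-gated
    cell-death models turn the dose field into death-radius-versus-duration
    curves: a One-Step model (death when cumulative energy density reaches
    Wth) and a Two-Step model (energy accumulates only while the instantaneous
    power density exceeds Pth). Includes grid-search fitting of (Pth, Wth) to
    radius-versus-duration data, estimation of duration-dependent effective
    power thresholds at short durations, a synthetic-experiment generator for
    end-to-end validation, SPICE netlist export, and ggplot2 visualisations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, tidyr, knitr, rmarkdown
Config/testthat/edition: 3
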