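Package: dropfreeze
Title: Analysis and Simulation of Immersion-Mode Drop-Freezing Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for cold-stage drop-freezing (immersion freezing) assays
    of ice-nucleating particles. Converts per-droplet freezing temperatures
    into frozen-fraction curves and cumulative ice-nucleus concentration
    spectra K(T) via the Vali equation, with exact binomial confidence
    bounds, onset and median (T50) freezing temperatures, and paired
    control/treatment comparisons (heat- and filtration-sensitive fractions,
    Welch and bootstrap tests). Includes a singular-model simulator that
    generates synthetic assays from mixtures of ice-nucleus populations
    with Poisson loading, plus heat and filtration treatment operators and
    calibrated preset scenarios, so the full pipeline is testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
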