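Package: phycotherm
Title: Thermal Performance, Microbiome Diversity and Metabolite Shifts in
    Algal Host-Microbiome Adaptation Experiments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for long-term warming-adaptation experiments
    on phytoplankton hosts and their bacterial microbiomes. Estimates
    specific growth rates from cell-count time series by log-linear
    regression over an automatically detected exponential window, fits the
    Norberg/Eppley thermal performance curve to growth-rate-vs-temperature
    observations by multi-start least squares and derives thermal traits
    (maximum growth rate, optimal temperature, critical thermal limits,
    80 percent performance breadth) numerically, computes alpha diversity
    (richness, Shannon, Smith-Wilson Evar), extinction and shared-taxon
    accounting, Bray-Curtis distances and permutation PERMANOVA from ASV
    count tables, and metabolite class fractions and fold changes from
    concentration tables. Includes a seeded synthetic-data generator with
    the statistical structure the analysis assumes, and a configuration
    driven command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
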