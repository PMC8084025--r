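Package: frogniche
Title: Thermal and Hydric Niche Analysis for Terrestrial-Breeding Frogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the thermal and hydric niche of
    terrestrial-breeding amphibians from laboratory and field data. Fits a
    five-parameter unimodal development-rate curve to incubation experiments
    under constant and fluctuating temperature regimes (rate summation),
    extracts the thermal optimum and an extrapolated critical thermal
    maximum, estimates the water absorption threshold from water-flux
    experiments on wetted substrates, converts soil volumetric water content
    to water potential via van Genuchten retention curves, summarises
    threshold exceedance in soil microclimate logger series (including
    warming tolerance and rank correlations with population size), reduces
    agar-model deployments to standardised daytime water-loss rates, and
    provides nonparametric climate trend statistics (Mann-Kendall, Sen's
    slope, baseline anomalies, percentile ranks). Seeded synthetic-data
    generators emulate every input with known ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
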