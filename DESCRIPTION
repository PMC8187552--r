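Package: ncpbudget
Title: Upper-Ocean Carbon-Nitrogen-Phosphorus Budgets from Nanomolar
    Nutrient Fluxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for closing annual carbon, nitrogen and phosphorus
    budgets of the subtropical upper ocean from shipboard time-series
    casts and microstructure turbulence profiles. Computes mixed layer
    and euphotic zone depths, salinity-normalized trapezoidal
    inventories, Osborn vertical diffusivity (Kz = 0.2 epsilon/N^2) and
    turbulent diffusive nutrient fluxes at nanomolar concentration
    gradients, integrates fluxes over sea-surface-temperature regimes
    into annual influxes, and derives net community production
    requirements, microbial elemental demand and recycling factors with
    95 percent confidence-interval error propagation. Includes a seeded
    synthetic cruise-data generator emulating an oligotrophic 24N
    transect so the full pipeline runs without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
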