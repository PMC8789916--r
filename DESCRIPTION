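Package: hotbio
Title: Radiotracer Rates, Sulfate Budgets, and Bioenergetics of Deep Hot
    Subseafloor Sediment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative toolkit for microbial activity in deeply buried,
    hot marine sediment. Computes volumetric sulfate-reduction and
    methanogenesis rates from 35S/14C radiotracer slurry incubations with a
    killed-control detection-limit statistic, evaluates a diffusion-based
    porewater sulfate budget (half-space error-function solution plus a
    finite-difference cross-check), calculates in-situ Gibbs energies of
    the catabolic reactions with extended Debye-Hueckel activity
    coefficients, converts rates and cell counts into per-cell metabolic
    rates, thermal-damage repair thresholds and biomass turnover times,
    and ships a seeded synthetic-data generator so the full pipeline runs
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
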