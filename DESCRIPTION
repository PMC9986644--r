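Package: soilPTE
Title: Pollution Indices, Ecological and Human Health Risk, and Source
    Apportionment for Potentially Toxic Elements in Urban Soil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Appraisal of potentially toxic elements (As, Cd, Pb, Cr, Ni,
    Cu) in urban soils: classical pollution indices (contamination factor,
    degree of contamination, enrichment factor, geoaccumulation index,
    pollution load index), Hakanson potential ecological risk, USEPA
    multi-route (ingestion, dermal, inhalation) human health risk for
    child and adult receptors, and a positive matrix factorization (PMF)
    receptor model with measurement-uncertainty weighting for source
    apportionment. Ships study-area reference tables, a synthetic sample
    generator with per-land-use truncated-normal targets, and an
    end-to-end pipeline producing machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'eco-risk.R'
    'health-risk.R'
    'indices.R'
    'pipeline.R'
    'pmf.R'
    'reference-set.R'
    'schemes.R'
    'soil-samples.R'
    'soilPTE-package.R'
    'synthetic.R'
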