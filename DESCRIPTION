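Package: occbias
Title: Taxonomic Bias Auditing of Primary Biodiversity Occurrence Data
Version: 0.1.0
Authors@R: person("occbias", "developers", role = c("aut", "cre"),
    email = "occbias@example.org")
Description: Tools to audit taxonomic sampling bias in primary biodiversity
    occurrence data (GBIF-style Darwin Core tables). Normalizes occurrence
    records with data-origin and completeness flags, computes per-taxon bias
    statistics including deviation from an ideal species-proportional
    sampling and a spatially-distinct-occurrence criterion on an Eckert IV
    equal-area 10 km grid, tracks the temporal evolution of the bias,
    relates record quality and origin through multiple correspondence
    analysis with rare-category ventilation, and fits negative-binomial
    regressions of occurrence counts on public-interest and research-effort
    covariates. A seeded synthetic-data generator emulates the statistical
    structure of large occurrence snapshots at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
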