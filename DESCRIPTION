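Package: compostom
Title: Multi-Technique Assessment of Organic-Matter Biodegradation During Composting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to follow organic-matter transformation during composting of
    agro-industrial wastes by combining classical chemical maturity indices
    (humification ratio and index, percentage of humic acids, polymerisation
    rate, organic-matter loss by ash balance), first-order degradation
    kinetics, the exothermic index from pile/ambient temperature records,
    thermal stability indices (R1/R2) from TG/DTG/DTA thermograms, FT-IR
    relative-absorbance band profiles, and solid-state CPMAS 13C NMR
    chemical-shift-region integration. Includes seeded synthetic-data
    generators for all five input kinds with known ground truth, and a
    pipeline that consolidates per-pile, per-phase results into a single
    report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    signal,
    pracma,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
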