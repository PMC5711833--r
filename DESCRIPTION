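Package: thermosip
Title: Thermodynamics and 13C Source Partitioning of Soil Microbial
    Carbon Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies soil microbial carbon use from combined isothermal
    calorimetry, 13C-glucose tracing, and DNA stable isotope probing (SIP)
    incubation experiments. Integrates calorimeter power curves to
    cumulative heats and computes thermodynamic efficiency indices, thermal
    yields, calorespirometric ratios, and metabolic quotients; partitions
    respired CO2-C into glucose-derived, soil organic matter derived, and
    primed pools by 13C mass balance; analyses SIP-fraction OTU tables
    (rarefaction, Bray-Curtis dissimilarity, principal coordinate analysis,
    PERMANOVA, a permutation-based differential abundance screen, and
    Spearman correlation maps against soil attributes); and simulates
    complete experiments with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
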