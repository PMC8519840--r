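Package: nutrigeo
Title: Geometric Framework Analysis of Nutrient Regulation in Feeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing how caged animals regulate their intake of two
    nutrients (amino acids and carbohydrate) when confined to single, nutritionally
    imbalanced liquid diets. Builds molar amino-acid:carbohydrate diet panels,
    converts raw feeder-tube masses into evaporation-corrected per-individual
    nutrient intakes, fits intake arrays across diets and tests their slopes
    against the diagnostic rules of compromise of the geometric framework of
    nutrition (no-interaction, equal-distance, closest-distance), characterises
    array shape as a function-valued trait (peak, height, tolerance, strength),
    and simulates complete feeding trials from agents feeding under a known rule
    so every stage of the pipeline can be verified by parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
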