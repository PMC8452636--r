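Package: froienc
Title: Image-Computable Encoding Models of Category-Selective Visual Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and evaluates image-computable encoding models of the mean
    response of category-selective regions of the human ventral visual stream
    (fusiform face area, parahippocampal place area, extrastriate body area).
    Provides session normalization of per-stimulus response estimates,
    split-half noise ceilings with Spearman-Brown correction, a fast ridge
    mapper for screening feature spaces, a two-stage factorized spatial-by-
    channel linear readout with a cross-hemisphere locking protocol,
    cross-validated predictivity metrics at several grains, within-category
    shuffle controls, representational dissimilarity analysis, rater-based
    predictor scoring, and model-driven probing tools: ranked image screening,
    selective-unit controls, generator-coupled activation-maximization
    synthesis, and randomized-mask importance maps. A seeded synthetic-data
    module generates stimulus catalogs, toy feature extractors, ground-truth
    mappings and multi-run response tables so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
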