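Package: skindiurnal
Title: Diurnal Rhythms and Their Variability in Two-Layer Skin Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects population-level 24 h (diurnal) rhythms in dermis and
    epidermis gene expression relative to internal, chronotype-corrected
    time; tests for layer-differential rhythmicity; decomposes inter-subject
    versus inter-layer variability of rhythm parameters with per-gene linear
    mixed models and delta-method error propagation; runs hypergeometric
    over-representation and Kuiper-test phase set enrichment; and trains a
    small-biomarker sparse-principal-component predictor of internal time
    from a single sample. Includes a synthetic cohort generator with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
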