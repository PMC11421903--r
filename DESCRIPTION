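Package: rumblesig
Title: Vocal Signatures in Female Elephant Rumbles Across Nested Social Tiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to test for vocal signatures of individual, core-group,
    bond-group and population identity in low-frequency harmonic calls
    (rumbles) of female African elephants. Provides a synthetic-call and
    social-structure simulator, mel-spectrogram and second-harmonic contour
    feature extraction, social-tier inference from sighting data via simple
    ratio association indices and Ward clustering, leakage-proof random-forest
    classification experiments against a majority-classifier null with exact
    binomial tests, and random-forest proximity-score call-similarity analyses
    using gamma mixed models that separate social from genetic influences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    ranger,
    glmmTMB,
    emmeans,
    tibble,
    rlang
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
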