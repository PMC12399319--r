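Package: dunesync
Title: Demographic Asynchrony, Portfolio Effects and Climate Drivers in
    Zoned Plant Censuses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify small-scale demographic asynchrony in a
    zoned long-term census of a monocarpic perennial plant.  Builds
    plant-year transitions from tagged-individual census tables, fits the
    five vital rates (seedling survival, plant survival, growth, flowering
    probability, new-plant size) as mixed models with year-by-zone
    variation, assembles zone- and year-specific integral projection
    models with discrete seedling and adult stages, and computes
    population synchrony, Taylor mean-variance scaling and the portfolio
    effect.  A sliding-window climate analysis selects the climate
    variable and absolute monthly window best predicting each vital rate
    by AICc against a climate-free baseline, with a year-randomization
    test for spurious support, and an attribution step regresses per-zone
    climate coefficients on each zone's correlation with the foredune
    zone.  Includes an individual-based synthetic census generator with
    retrievable true parameters for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
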