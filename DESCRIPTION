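Package: catadjust
Title: Category Adjustment Models of Color Memory Across Languages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Bayesian category-adjustment modeling of color reconstruction and
    discrimination from memory. Builds a one-dimensional perceptual hue
    spectrum from Munsell-indexed stimuli via xyY and CIELAB (CIE76 delta-E
    spacing, normalized to unit length), implements Gaussian memory-trace and
    Gaussian category reconstruction models (null, 1-category, 2-category
    mixture posteriors), fits category components to color-naming data and
    memory uncertainty to reconstruction-bias or two-alternative forced-choice
    discrimination data, simulates 2AFC discrimination through a Luce choice
    rule for cross-language comparisons (English, Berinmo, Himba), and
    generates synthetic naming, bias, and discrimination datasets from known
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
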