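Package: cryptobee
Title: Morphometric and DNA-Barcode Discrimination of Cryptic Bumble Bees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative separation of the cryptic North American bumble bees
    Bombus sandersoni, B. vagans and B. perplexus from malar and antennal
    measurements. Computes the three malar ratio statistics (MRL, MR1, MR3),
    fits two-class linear discriminant models with stratified 60/40
    train/test evaluation and bootstrap accuracy estimation, builds
    bootstrap-and-simulate 99% predictive reference ranges with a
    range-plus-hair-trait identification rule, compares species, caste and
    region means with Gaussian linear models, Type II ANOVA and
    Tukey-adjusted marginal-mean contrasts, quantifies observer
    repeatability, and performs desk-scale COI barcode haplotype analysis
    (haplotype collapse, percent identity, minimum-spanning haplotype
    networks). A synthetic specimen generator calibrated to published
    distribution parameters for the three species makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    car,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
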