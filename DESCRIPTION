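Package: patchpk
Title: Noncompartmental Pharmacokinetics and Tissue Statistics for
    Transdermal Patches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for single-application transdermal patch
    studies: noncompartmental pharmacokinetic (NCA) parameter estimation
    with automated terminal-phase selection, patch mass-balance
    percutaneous absorption ratios, power-model dose-proportionality
    assessment, and below-limit-of-quantification (BLQ) aware two-group
    tissue-concentration comparisons with Welch's t test. Includes a
    synthetic transdermal pharmacokinetic trial generator (zero-order
    input, one-compartment disposition, lognormal between-subject and
    residual variability) so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
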