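Package: varconcord
Title: Cross-Platform Validation of Expressed Variants and Gene Fusions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating variant and fusion detection from
    expressed RNA against orthogonal platforms in small clinical
    specimens such as thyroid fine-needle aspirates. Harmonizes matched
    DNA/RNA call sets across sequencing platforms, computes positive and
    negative percent agreement and confirmation rates with exact
    (Clopper-Pearson) binomial confidence intervals, classifies
    allelic-expression imbalance from paired DNA:RNA variant allele
    frequencies, quantifies replicate and between-laboratory
    reproducibility of qualitative calls, and derives histology-anchored
    diagnostic performance stratified by cytology category and
    classifier call. A seeded synthetic-cohort generator simulates
    matched ground-truth call sets with realistic read-depth and
    allele-expression structure so every pipeline stage is testable
    without access to proprietary specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
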