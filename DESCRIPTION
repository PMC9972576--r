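Package: methylstab
Title: Longitudinal Stability Analysis of DNA Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the intra-individual, long-term stability of
    DNA methylation measured on Illumina-style beadchip arrays from paired
    samples collected at two time points. Implements per-CpG intra-class
    correlation screening (two-way mixed, single-measures, consistency form)
    with F-tests, confidence intervals and reliability classification;
    gap-based detection of genotype-driven probe signals; reference-based
    leukocyte deconvolution by non-negative least squares; covariate-adjusted
    paired differential methylation with empirical-Bayes variance moderation;
    CpG-set rank tests and probe-bias-corrected gene-set enrichment; and a
    synthetic paired-cohort generator with known ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
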