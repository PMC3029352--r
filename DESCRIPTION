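Package: nodclass
Title: Expression Classes and Activation Patterns in Legume Nodule Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-color microarray transcriptomes of
    Medicago truncatula root nodules induced by wild-type and mutant
    Sinorhizobium meliloti strains. Calls per-condition differential
    expression against control roots (one-sample t-statistics with
    Benjamini-Hochberg correction), assigns every regulated probe to one of
    sixteen mutually exclusive expression classes from its call pattern
    across a seven-condition nodule panel, clusters condition profiles with
    Pearson correlation and average linkage, scores qualitative concordance
    between platforms, classifies qRT-PCR root expression profiles into
    activation/repression archetypes via delta-delta-Ct relative
    quantification, and tabulates census reports (class counts, regulator
    cross-tabs, percentage columns). Includes a synthetic-data generator
    that plants known class and pattern memberships so the whole pipeline is
    testable end to end without external array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
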