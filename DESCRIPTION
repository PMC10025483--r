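Package: mirpare
Title: Small RNA and Degradome Analysis of miRNA Responses to Drought and
    Rehydration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained pipeline for conserved microRNA analysis from
    small-RNA sequencing libraries in a drought/rehydration experimental
    design: read trimming and collapsing, conserved-miRNA identification by
    exact containment matching against a mature reference with isomiR
    collapsing, negative-binomial Wald differential-accumulation testing with
    median-of-ratios normalization and Benjamini-Hochberg adjustment,
    restoration analysis after rewatering, degradome (PARE) cleavage-site
    profiling with t-plot views and competition-ranked sites, miRNA:target
    duplex alignment with a 0-18 compliance score, and 2^-ddCt qPCR
    fold-change integration with miRNA/target anticorrelation calls. A
    synthetic-data generator reproduces the statistical structure of the
    assumed study design (12 libraries, 3 replicates x 4 conditions) so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
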