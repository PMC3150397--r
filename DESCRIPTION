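Package: arsig
Title: Androgen-Response Expression Signatures from Two-Color Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for androgen-receptor target-gene signatures in
    prostate cancer cell line panels profiled on two-color spotted oligoarrays.
    Implements per-subarray lowess normalization, global median scaling with an
    intensity floor, low-intensity spot exclusion, dye-swap discordance
    filtering and replicate averaging; a fold-change signature caller with a
    one-class Significance Analysis of Microarrays (SAM) permutation FDR;
    cross-study concordance clustering with progression-cluster assignment;
    and qPCR standard-curve quantification with reference-gene normalization
    and ordered-group tests. A spot-level simulator with planted truth makes
    every stage testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
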