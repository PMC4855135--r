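Package: cladeqpcr
Title: Design and Evaluation of Clade-Specific qPCR Primer Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating clade-specific quantitative
    PCR (qPCR) primer sets against clade-annotated marker-gene reference
    databases. Implements in-silico PCR under configurable mismatch-allowance
    patterns with 3'-protected windows, coverage and specificity reporting,
    candidate primer-pair ranking with thermodynamic screening, qPCR
    standard-curve fitting and amplification-efficiency estimation, a
    relative-efficiency interference statistic, rrn-copy-number-normalized
    clade abundance estimation, and nearest-reference clade assignment of
    cloned amplicons. A synthetic clade-structured sequence simulator and a
    threshold-cycle simulator allow the full workflow to be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
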