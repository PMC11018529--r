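Package: subgenomeBias
Title: Subgenome Expression Dominance Analysis for Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of homoeolog expression bias and subgenome dominance in
    allopolyploid transcriptomes. Implements TPM normalization and
    expressed-gene filtering, homoeolog pair log-ratios, triad relative
    expression with nearest-ideal-point bias categories (balanced, dominant,
    suppressed), expression-shift clustering of homoeolog profiles with
    ploidy-matched subsampling, a lightweight weighted co-expression network
    (biweight midcorrelation, signed-hybrid adjacency, topological overlap,
    module eigengenes, KME hubs, neighbor subgenome composition), and
    sliding-window gene-retention (fractionation-bias) tracks. A seeded
    synthetic-data generator with truth tables makes every stage verifiable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
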