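Package: cernet
Title: Competing Endogenous RNA Network Inference from RNA-Seq Counts
Version: 0.1.0
Authors@R: person("cernet", "developers", role = c("aut", "cre"),
    email = "cernet@example.org")
Description: An integrative lncRNA-miRNA-mRNA analysis pipeline for small
    grouped RNA-seq designs: candidate long non-coding RNA filtering,
    negative-binomial differential expression with Benjamini-Hochberg
    correction, correlation-based trans-target inference, seed-weighted
    miRNA binding-site scanning with score and free-energy thresholds,
    competing-endogenous-RNA network assembly with target/decoy lncRNA
    classification and bridge-gene detection, QTL interval co-localization,
    and hypergeometric over-representation testing. Ships a synthetic-study
    generator that plants known differential expression, binding sites and
    ceRNA triads so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ape,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
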