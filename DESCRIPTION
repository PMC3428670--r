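Package: wlinker
Title: Identification of W-Linked Contigs by Male Read-Depth Subtraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies female-specific (W-linked) contigs in a heterogametic
    (ZW) genome assembly by aligning short reads from the homogametic (ZZ) sex
    and looking for contigs that recruit almost no uniquely mapping reads.
    Provides reference masking and uniqueness filtering, a seed-and-extend
    unique-placement read mapper, per-contig coverage and normalized read-depth
    features, bootstrap separation statistics, a length-conditioned naive Bayes
    classifier with discretized feature distributions, ROC/AUC evaluation
    harnesses, and a fully labeled synthetic ZW/ZZ data generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
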