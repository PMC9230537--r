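Package: rbpdetect
Title: Identification of Phage Receptor-Binding Proteins by Profile HMMs
    and Gradient Boosting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two complementary tracks for identifying receptor-binding
    proteins (RBPs, i.e. tail fibers and tailspikes) in annotated phage
    genomes. A domain-based track builds and scores profile hidden Markov
    models (with HMMER3 ASCII interoperability) and augments a curated
    domain set with custom HMMs constructed from one-sided domain
    architectures. A machine-learning track trains a gradient-boosted
    binary classifier on fixed-length protein embeddings, optionally fused
    with HMM bit scores, under nested cross-validation. Includes the
    annotation-curation pipeline that labels and filters GenBank coding
    sequences, an evaluation harness (F1, MCC, sensitivity, specificity,
    PR-AUC, multi-method concordance), and deterministic synthetic-data
    generators so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
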