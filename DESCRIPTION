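Package: selfbin
Title: Self-Training Composition-Based Taxonomic Binning of Metagenome
    Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-phase taxonomic binning of assembled metagenome contigs.
    Phase one labels a trusted subset of the sample via marker-gene regions
    using a bootstrap-confidence naive Bayes classifier, enforces
    scaffold-contig assignment consistency, and automatically selects the
    taxa to model together with balanced sample-derived training data.
    Phase two trains a top-down hierarchical composition classifier over
    4-6-mer frequency profiles and bins the whole sample.  Includes a
    one-pass rolling-index algorithm counting k-mers of several consecutive
    lengths simultaneously, per-rank (corrected) precision/recall and
    scaffold-contig agreement evaluation, and a seeded synthetic-community
    generator for benchmarking without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    glmnet,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
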