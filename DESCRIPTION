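Package: sirnadesign
Title: Design, Off-Target Screening and Knockdown Validation of siRNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for small interfering RNA (siRNA) design and
    validation against annotated transcript sequences. Enumerates 21-nt
    candidate duplexes, scores them with a trainable DSIR-style linear
    efficacy model over position-specific nucleotides and guide-strand
    motifs, and corrects predicted efficacy for the target-site location
    (5'UTR/CDS/3'UTR) and its distance from the transcript 5' end.
    Screens candidates against a transcript databank with a bit-parallel
    shift-add mismatch search and profiles heptamer seed matches in
    3'UTRs. Computes knockdown (extinction) estimates from qPCR
    cycle-threshold data with dual reference-gene normalization, and
    fits the covariate linear models (with ANOVA term tests) that relate
    measured efficacy to target-site features. A synthetic-data module
    generates transcriptomes, planted off-target sites, Ct tables and
    efficacy panels for fully reproducible in-silico studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
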