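Package: vbsnv
Title: Rare Variant Calling with a Hierarchical Beta-Binomial Model and
    Variational EM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates position-specific non-reference allele frequencies
    (NRAF) from replicated deep-sequencing read counts under a hierarchical
    Bayesian Beta-Binomial model, using a non-conjugate coordinate-ascent
    variational EM algorithm with a numerically integrated evidence lower
    bound. Rare single nucleotide variants are called by a posterior
    difference test between a case and a control sample, with a chi-squared
    non-uniform base distribution filter to screen out indiscriminate
    sequencing errors. Includes readers for samtools text pileup and
    tab-delimited depth-chart count tables, a minimal VCF writer, a
    generative-process simulator for benchmarking, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
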