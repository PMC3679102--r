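Package: kaksflow
Title: Ortholog Detection and Ka/Ks-Based Positive Selection Screening for
    Transcriptome Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for detecting rapidly evolving genes between the
    transcriptomes of two closely related species. Provides FASTQ read
    cleaning, longest-ORF coding-region extraction, reciprocal-best-hit
    orthology with strict paralog filtering, codon-aware alignment,
    Ka/Ks estimation by Nei-Gojobori counting and by the Yang-Nielsen
    approximate maximum-likelihood method, Fisher exact validity testing
    and GO category enrichment, and RPKM-based expression concordance
    between stress and control conditions. Includes a codon-substitution
    simulator that generates ortholog pairs, paralog decoys, and
    sequencing reads with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
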