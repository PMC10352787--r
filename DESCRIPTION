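Package: gtai
Title: Species-Specific tRNA Adaptation Index by Genetic-Algorithm Weight
    Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the tRNA adaptation index (tAI) with species-specific
    codon-anticodon coupling efficiencies (S_ij) inferred by a genetic
    algorithm that maximises the Spearman correlation between the relative
    synonymous codon usage (RSCU) of a low-ENc reference gene set and the
    absolute adaptiveness (W_i) of each codon given the genome's tRNA gene
    copy numbers.  Ships the supporting codon-usage statistics (RSCU,
    improved effective number of codons, CAI, SCUO, GC content), Williams'
    test and repeated-subsampling correlation comparisons, and a
    synthetic-genome simulator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
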