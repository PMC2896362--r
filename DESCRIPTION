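Package: protpipe
Title: Differential Proteomics from 2-D Gel Spots to Pathways, Networks and
    Bayesian Fold-Change Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale re-implementation of a classic comparative
    proteomics inference chain for two-condition 2-D gel experiments:
    spot-volume normalization and fold-change filtering, peptide-mass-
    fingerprint protein identification (in-silico tryptic digestion,
    ppm-window matching, batch background-peak elimination, three scoring
    algorithms with a two-of-three consensus rule, and an Mr/pI
    plausibility check), canonical-pathway over-representation by
    right-tailed Fisher's exact test with Benjamini-Hochberg correction,
    greedy focus-protein network construction scored as -log10 of a
    hypergeometric p-value, and empirical-Bayes Metropolis MCMC estimation
    of a densitometry expression ratio with adaptive proposal scaling and
    the Gelman-Rubin convergence diagnostic.  A synthetic-data module
    generates every input (protein FASTA, peak lists, spot tables, a
    pathway/interaction knowledgebase, densitometry replicates) with
    planted ground truth so the whole chain is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    igraph,
    Biostrings,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
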