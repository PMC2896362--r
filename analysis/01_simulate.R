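#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-condition proteomics study.
#
# Emulates the raw material of a comparative 2-D gel experiment on two
# cell lines: 60 matched spots over a 60-protein database with 10 spots
# planted as differentially expressed at 2-fold under 10% multiplicative
# noise, one MALDI peak list per spot (70% peptide detection, 10 ppm
# mass jitter, 6 shared contaminant peaks at 15% occurrence), a
# 12-pathway knowledgebase whose first pathway is enriched for the
# planted proteins, a 240-edge interaction graph concentrating them in
# one community, and 6 densitometry replicates at a true log10 ratio of
# log10(1.4).

suppressPackageStartupMessages(library(protpipe))

seed <- 1L
study <- make_synthetic_study(seed = seed)
paths <- write_study(study, "results/synthetic_study")

cat("Synthetic study written to results/synthetic_study (seed", seed,
    ")\n")
cat("  proteins:", length(study$db), " spots:", nrow(study$spots),
    " peak lists:", length(study$peaks$peak_lists), "\n")
cat("  planted de proteins:",
    paste(study$truth$de_proteins, collapse = " "), "\n")
cat("  planted pathway:", study$truth$enriched_pathways,
    " true log10 ratio:", round(study$truth$true_R, 4), "\n")
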