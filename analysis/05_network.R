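#!/usr/bin/env Rscript
# Stage 5: focus-protein interaction networks.
#
# Networks are grown greedily from the interaction graph to include as
# many focus proteins as possible (plus the non-focus connectors needed
# for connectivity, capped at 35 nodes), scored as -log10 of the
# hypergeometric probability of their focus content, and flagged
# significant at score >= 6 (p < 1e-6).  Nodes connecting to at most one
# other node are classified as hanging.

suppressPackageStartupMessages(library(protpipe))

analysis <- read.csv("results/spots_analysis.csv")
ids <- read.csv("results/identifications.csv")
focus <- unique(na.omit(ids$accession[match(analysis$spot_id,
                                            ids$spot_id)]))
edges <- read_sif("results/synthetic_study/interactions.sif")
db <- read_fasta("results/synthetic_study/proteins.fasta")
g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                   vertices = sort(names(db)))

res <- grow_networks(g, focus, max_size = 35, score_cutoff = 6)
write.csv(res$summary, "results/networks_summary.csv", row.names = FALSE)
attrs <- do.call(rbind, lapply(seq_along(res$networks), function(i) {
  nw <- res$networks[[i]]
  data.frame(network_id = i, accession = nw$nodes,
             is_focus = nw$nodes %in% nw$focus_nodes,
             hanging = nw$nodes %in% nw$hanging)
}))
write.csv(attrs, "results/networks_nodes.csv", row.names = FALSE)

cat(nrow(res$summary), "network(s) grown from", length(focus),
    "focus proteins over a", igraph::vcount(g), "-node graph\n")
print(res$summary, row.names = FALSE, digits = 4)
nw1 <- res$networks[[res$summary$network_id[1]]]
cat("  top network hanging nodes:",
    if (length(nw1$hanging)) paste(nw1$hanging, collapse = " ")
    else "none", "\n")
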