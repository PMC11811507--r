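#!/usr/bin/env Rscript
# Stage 4: template-constrained pathway enumeration.
#
# All simple directed paths from marker proteins to the stage-3 enzymes are
# enumerated against the four default templates (direct regulation,
# expression regulation, and their single-intermediate mediated variants)
# over the typed interaction graph.

suppressMessages(library(metaboreg))

graph <- read_graph_file("results/inputs/graph.tsv")
part <- jsonlite::read_json("results/sets/marker_partition.json",
                            simplifyVector = TRUE)
markers <- sort(unique(c(part$A_only, part$B_only, part$shared)))
enzymes <- read.delim("results/sets/enzymes.tsv")$enzyme_protein_id

paths <- enumerate_all_templates(graph, sources = markers, targets = enzymes)
cat(sprintf("%d regulatory pathways (%d markers -> %d enzymes)\n",
            nrow(paths), length(unique(paths$marker)),
            length(unique(paths$enzyme))))
print(table(paths$template))

dir.create("results/pathways", showWarnings = FALSE)
write_paths(paths, "results/pathways/paths.tsv")
# subnetwork spanned by the discovered pathways, for network viewers
sub <- subgraph_between(graph, markers, enzymes, max_len = 3)
write_graph_file(sub, "results/pathways/subnetwork.sif", format = "sif")
cat("Paths and SIF subnetwork written under results/pathways/\n")
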