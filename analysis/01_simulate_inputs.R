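#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# The cohort's plasma panel is not redistributable, so this stage builds a
# synthetic stand-in at the study design: 9 PD / 9 VP / 17 control samples
# over the 44-analyte amino-acid + acylcarnitine panel, with the published
# significance pattern planted as 2.0 natural-log shifts (cv 0.3); marker
# lists of 84 (PD) and 60 (VP) gene symbols with exactly 22 shared; and a
# typed interaction graph planting 120 template pathways from markers to the
# enzymes of the shipped metabolite->enzyme map.

suppressMessages(library(metaboreg))

seed <- 1L
dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)

panel <- simulate_study_panel(seed = seed)
write_profiles(panel, "results/inputs/panel.tsv", format = "tsv")
print(panel)

ml <- simulate_marker_lists(84, 60, 22, seed = seed + 1L)
write_marker_list(ml$listA, "results/inputs/markers_pd.txt")
write_marker_list(ml$listB, "results/inputs/markers_vp.txt")
cat(sprintf("Marker lists: %d PD, %d VP, %d shared\n",
            length(ml$listA), length(ml$listB),
            length(intersect(ml$listA, ml$listB))))

emap <- read_enzyme_map()
sim <- simulate_marker_enzyme_graph(
  markers = toupper(c(ml$listA, ml$listB)),
  enzymes = unique(emap$enzyme_protein_id),
  n_paths = 120, n_intermediates = 15, random_edge_prob = 0,
  seed = seed + 2L)
write_graph_file(sim$graph, "results/inputs/graph.tsv", format = "edge_tsv")
print(sim$graph)
cat("Inputs written under results/inputs/\n")
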