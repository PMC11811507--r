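# complete simulated input bundle on disk, used by the pipeline and
# end-to-end determinism tests
write_demo_inputs <- function(dir, seed = 1) {
  panel_file <- file.path(dir, "panel.tsv")
  write_profiles(simulate_study_panel(seed = seed), panel_file, format = "tsv")
  ml <- simulate_marker_lists(84, 60, 22, seed = seed + 1)
  fa <- file.path(dir, "markers_pd.txt"); write_marker_list(ml$listA, fa)
  fb <- file.path(dir, "markers_vp.txt"); write_marker_list(ml$listB, fb)
  emap <- read_enzyme_map()
  sim <- simulate_marker_enzyme_graph(
    markers = toupper(c(ml$listA, ml$listB)),
    enzymes = unique(emap$enzyme_protein_id),
    n_paths = 120, n_intermediates = 15, random_edge_prob = 0,
    seed = seed + 2)
  gf <- file.path(dir, "graph.tsv")
  write_graph_file(sim$graph, gf, format = "edge_tsv")
  list(profiles = panel_file, markers_a = fa, markers_b = fb, graph = gf)
}
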