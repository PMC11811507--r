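test_that("panel simulation is reproducible and honours the planted design", {
  cfg <- panel_sim_config(effect_metabolites_A = c("Ala", "Pro"),
                          log_fold_shift = 2, cv = 0.3, seed = 11)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$concentrations, p2$concentrations)
  expect_identical(p1$groups, p2$groups)
  expect_true(all(p1$concentrations > 0))
  expect_equal(dim(p1$concentrations), c(35L, 44L))
  expect_equal(unname(table(p1$groups)[c("diseaseA", "diseaseB", "control")]),
               c(9L, 9L, 17L), ignore_attr = TRUE)
  # planted shift moves the group-A mean of planted metabolites, not others
  ga <- p1$groups == "diseaseA"; gc <- p1$groups == "control"
  lfc <- log(colMeans(p1$concentrations[ga, ])) -
    log(colMeans(p1$concentrations[gc, ]))
  expect_true(all(lfc[c("Ala", "Pro")] > 1))
  expect_true(all(abs(lfc[setdiff(names(lfc), c("Ala", "Pro"))]) < 1))
})

test_that("different seeds give different panels", {
  cfg1 <- panel_sim_config(seed = 1)
  cfg2 <- panel_sim_config(seed = 2)
  expect_false(identical(simulate_panel(cfg1)$concentrations,
                         simulate_panel(cfg2)$concentrations))
})

test_that("panel config rejects invalid designs", {
  expect_error(panel_sim_config(group_sizes = c(1, 9, 17)), "group sizes")
  expect_error(panel_sim_config(cv = 0), "cv")
  expect_error(panel_sim_config(effect_metabolites_A = "NotAMetabolite"),
               "not in panel")
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_panel(panel_sim_config(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("marker list simulation gives exact overlap and partition sizes", {
  ml <- simulate_marker_lists(84, 60, 22, seed = 3)
  expect_length(ml$listA, 84)
  expect_length(ml$listB, 60)
  expect_length(intersect(ml$listA, ml$listB), 22)
  part <- partition_markers(ml$listA, ml$listB, labels = c("PD", "VP"))
  expect_length(part$A_only, 62)
  expect_length(part$B_only, 38)
  expect_length(part$shared, 22)

  same <- simulate_marker_lists(5, 5, 5, seed = 4)
  expect_setequal(same$listA, same$listB)
  disj <- simulate_marker_lists(3, 4, 0, seed = 5)
  expect_length(intersect(disj$listA, disj$listB), 0)
  expect_error(simulate_marker_lists(3, 4, 4), "n_shared")
})

test_that("noise-free planted graphs contain exactly the planted paths", {
  tpl <- default_templates()
  for (tid in names(tpl)) {
    cfg <- graph_sim_config(n_marker_proteins = 2, n_enzymes = 2,
                            n_intermediates = 1,
                            planted_paths = list(c("M1", "E1", tid)),
                            random_edge_prob = 0, seed = 7)
    sim <- simulate_knowledge_graph(cfg)
    paths <- enumerate_template_paths(sim$graph, tpl[[tid]],
                                      sources = sim$markers,
                                      targets = sim$enzymes)
    expect_equal(nrow(paths), 1L, info = tid)
    expect_equal(paths$marker, "M1", info = tid)
    expect_equal(paths$enzyme, "E1", info = tid)
  }
})

test_that("every planted path is recovered across all templates", {
  cfg <- graph_sim_config(n_marker_proteins = 3, n_enzymes = 2,
                          n_intermediates = 3,
                          planted_paths = list(c("M1", "E1", "T1"),
                                               c("M2", "E2", "T3"),
                                               c("M3", "E1", "T4")),
                          random_edge_prob = 0, seed = 8)
  sim <- simulate_knowledge_graph(cfg)
  paths <- enumerate_all_templates(sim$graph, sources = sim$markers,
                                   targets = sim$enzymes)
  expect_gte(nrow(paths), 3L)
  for (r in seq_len(nrow(sim$planted))) {
    hit <- paths$template == sim$planted$template[r] &
      paths$marker == sim$planted$marker[r] &
      paths$enzyme == sim$planted$enzyme[r]
    expect_true(any(hit), info = paste(sim$planted[r, ], collapse = "/"))
  }
})

test_that("graph simulation is deterministic and rejects bad configs", {
  cfg <- graph_sim_config(n_marker_proteins = 3, n_enzymes = 3,
                          n_intermediates = 2, n_noise_nodes = 2,
                          planted_paths = list(c("M1", "E2", "T3")),
                          random_edge_prob = 0.15, seed = 21)
  g1 <- simulate_knowledge_graph(cfg)
  g2 <- simulate_knowledge_graph(cfg)
  expect_identical(g1$graph$edges, g2$graph$edges)
  expect_error(graph_sim_config(planted_paths = list(c("M1", "E1", "T9"))),
               "template")
  expect_error(graph_sim_config(n_marker_proteins = 1,
                                planted_paths = list(c("M5", "E1", "T1"))),
               "marker")
  expect_error(graph_sim_config(random_edge_prob = 1.2), "random_edge_prob")
})

test_that("marker-enzyme graph plants paths between named symbols", {
  sim <- simulate_marker_enzyme_graph(c("SNCA", "LRRK2"), c("ALDH2", "BCAT1"),
                                      n_paths = 10, n_intermediates = 4,
                                      seed = 13)
  expect_equal(nrow(sim$planted), 10)
  paths <- enumerate_all_templates(sim$graph, sources = sim$markers,
                                   targets = sim$enzymes)
  planted_keys <- unique(with(sim$planted, paste(template, marker, enzyme)))
  found_keys <- unique(with(paths, paste(template, marker, enzyme)))
  expect_true(all(planted_keys %in% found_keys))
})
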