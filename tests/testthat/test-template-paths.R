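test_that("the default template set has the four pathway types", {
  tpl <- default_templates()
  expect_named(tpl, c("T1", "T2", "T3", "T4"))
  expect_length(tpl$T1$segments, 1)
  expect_equal(tpl$T2$segments[[1]]$edge_types, "expression_regulation")
  expect_equal(tpl$T2$segments[[2]]$edge_types, "encodes")
  # mediated templates require >= 1 intermediate
  expect_equal(tpl$T3$segments[[1]]$min, 1L)
  expect_equal(tpl$T4$segments[[1]]$min, 1L)
  expect_error(default_templates(0), "max_intermediates")
})

test_that("template validation rejects malformed specs", {
  expect_error(path_template("X", list()), "segment")
  expect_error(path_template("X", list(list(edge_types = "binds",
                                            node_type = "protein"))),
               "unknown edge type")
  expect_error(path_template("X", list(list(edge_types = "ppi",
                                            node_type = "gene"))),
               "terminate on a protein")
  expect_error(path_template("X", list(list(edge_types = "ppi",
                                            node_type = "protein",
                                            min = 2, max = 1))),
               "repeat range")
})

test_that("templates survive a YAML round trip", {
  tpl <- default_templates(max_intermediates = 2)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_templates(tpl, f)
  tpl2 <- read_templates(f)
  expect_named(tpl2, names(tpl))
  for (id in names(tpl))
    expect_equal(tpl2[[id]]$segments, tpl[[id]]$segments)
})

test_that("enumeration matches the worked single-path examples", {
  nodes <- data.frame(id = c("M", "X", "g", "E"),
                      type = c("protein", "protein", "gene", "protein"))
  edges <- data.frame(
    source = c("M", "X", "X", "g"),
    target = c("X", "M", "g", "E"),
    type = c("ppi", "ppi", "expression_regulation", "encodes"))
  g <- knowledge_graph(nodes, edges)
  tpl <- default_templates()

  p <- enumerate_template_paths(g, tpl$T4, "M", "E")
  expect_equal(nrow(p), 1)
  expect_equal(p$nodes, "M->X->g->E")
  expect_equal(p$length, 3L)

  # a parallel edge of a different type doubles the T4 paths
  edges2 <- rbind(edges, data.frame(source = "M", target = "X",
                                    type = "activity_regulation"))
  g2 <- knowledge_graph(nodes, edges2)
  p2 <- enumerate_template_paths(g2, tpl$T4, "M", "E")
  expect_equal(nrow(p2), 2)
  expect_setequal(p2$edge_types,
                  c("ppi;expression_regulation;encodes",
                    "activity_regulation;expression_regulation;encodes"))

  # T2 finds nothing (M has no expression edge), T1 nothing (no direct edge)
  expect_equal(nrow(enumerate_template_paths(g2, tpl$T2, "M", "E")), 0)
  expect_equal(nrow(enumerate_template_paths(g2, tpl$T1, "M", "E")), 0)
})

test_that("edgeless and missing-id inputs degrade gracefully", {
  g <- knowledge_graph(data.frame(id = c("A", "B"), type = "protein"), NULL)
  tpl <- default_templates()
  expect_equal(nrow(enumerate_template_paths(g, tpl$T1, "A", "B")), 0)
  expect_warning(p <- enumerate_template_paths(g, tpl$T1, c("A", "Zz"), "B"),
                 "Zz")
  expect_equal(nrow(p), 0)
})

test_that("enumeration equals the brute-force oracle on random typed graphs", {
  tpl <- default_templates(max_intermediates = 2)
  n_checked <- 0
  for (seed in 1:25) {
    g <- random_typed_graph(sample(6:12, 1), runif(1, 0.05, 0.25), seed)
    prot <- g$nodes$id[g$nodes$type == "protein"]
    if (length(prot) < 4) next
    sources <- prot[seq_len(min(3, length(prot) - 1))]
    targets <- prot[length(prot) - (0:1)]
    for (t in tpl) {
      got <- enumerate_template_paths(g, t, sources, targets)
      expect_equal(path_keys(got), oracle_template_paths(g, t, sources, targets),
                   info = sprintf("seed %d template %s", seed, t$id))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 60)
})

test_that("no path is emitted by two default templates", {
  tpl <- default_templates(max_intermediates = 2)
  for (seed in 1:10) {
    g <- random_typed_graph(10, 0.2, seed + 100)
    prot <- g$nodes$id[g$nodes$type == "protein"]
    if (length(prot) < 3) next
    sources <- prot[1:2]; targets <- prot[length(prot)]
    keys <- lapply(tpl, function(t)
      path_keys(enumerate_template_paths(g, t, sources, targets)))
    for (i in seq_along(keys))
      for (j in seq_len(i - 1))
        expect_length(intersect(keys[[i]], keys[[j]]), 0)
  }
})

test_that("adding an edge never decreases any template's path count", {
  set.seed(42)
  g <- random_typed_graph(9, 0.15, 999)
  prot <- g$nodes$id[g$nodes$type == "protein"]
  sources <- prot[1]; targets <- prot[length(prot)]
  tpl <- default_templates()
  base <- vapply(tpl, function(t)
    nrow(enumerate_template_paths(g, t, sources, targets)), 0L)
  # add a fresh protein-level edge
  cand <- expand.grid(s = prot, t = prot, stringsAsFactors = FALSE)
  cand <- cand[cand$s != cand$t, ]
  existing <- paste(g$edges$source, g$edges$target, "activity_regulation")
  cand <- cand[!paste(cand$s, cand$t, "activity_regulation") %in% existing, ]
  g2 <- knowledge_graph(g$nodes, rbind(g$edges, data.frame(
    source = cand$s[1], target = cand$t[1], type = "activity_regulation",
    sign = "unknown")))
  after <- vapply(tpl, function(t)
    nrow(enumerate_template_paths(g2, t, sources, targets)), 0L)
  expect_true(all(after >= base))
})

test_that("count matrices conserve the enumerated path total", {
  sim <- simulate_knowledge_graph(graph_sim_config(
    n_marker_proteins = 4, n_enzymes = 3, n_intermediates = 3,
    planted_paths = list(c("M1", "E1", "T1"), c("M1", "E2", "T3"),
                         c("M2", "E1", "T4"), c("M3", "E3", "T2")),
    random_edge_prob = 0.1, seed = 55))
  paths <- enumerate_all_templates(sim$graph, sim$markers, sim$enzymes)
  counts <- count_paths(paths)
  expect_equal(sum(counts$counts), nrow(paths))
  # margins equal an independent tally from the raw path list
  expect_equal(rowSums(counts$counts)[sort(unique(paths$marker))],
               vapply(split(paths$marker, paths$marker), length, 0L)[
                 sort(unique(paths$marker))])
  expect_equal(colSums(counts$counts)[sort(unique(paths$enzyme))],
               vapply(split(paths$enzyme, paths$enzyme), length, 0L)[
                 sort(unique(paths$enzyme))])
  # pair dedupe: at most one count per (template, marker, enzyme)
  dd <- count_paths(paths, dedupe = "pairs")
  expect_equal(sum(dd$counts),
               nrow(unique(paths[c("template", "marker", "enzyme")])))
})

test_that("empty path lists give an all-zero matrix", {
  counts <- count_paths(metaboreg:::empty_paths())
  expect_equal(sum(counts$counts), 0)
  expect_equal(dim(counts$counts), c(0L, 0L))
})
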