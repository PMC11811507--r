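tiny_graph <- function() {
  nodes <- data.frame(id = c("A", "B", "E", "gE"),
                      type = c("protein", "protein", "protein", "gene"))
  edges <- data.frame(
    source = c("A", "B", "B", "gE"),
    target = c("B", "A", "gE", "E"),
    type = c("ppi", "ppi", "expression_regulation", "encodes"),
    sign = c("unknown", "unknown", "up", "unknown"))
  knowledge_graph(nodes, edges)
}

test_that("constructor enforces the typed-graph invariants", {
  nodes <- data.frame(id = c("A", "B", "g"), type = c("protein", "protein", "gene"))
  ok <- function(s, t, ty) knowledge_graph(nodes, data.frame(
    source = s, target = t, type = ty))
  expect_error(ok("A", "B", "expression_regulation"), "gene node")
  expect_error(ok("g", "g", "encodes"), "self-loop")
  expect_error(ok("A", "g", "encodes"), "gene -> protein")
  expect_error(ok("A", "g", "ppi"), "two proteins")
  expect_error(ok("A", "C", "ppi"), "not declared")
  expect_error(ok("A", "B", "binds"), "unknown edge type")
  expect_error(knowledge_graph(data.frame(id = c("A", "A"),
                                          type = c("protein", "protein")),
                               NULL), "duplicate node")
  expect_error(ok(c("A", "A"), c("B", "B"), c("ppi", "ppi")), "duplicate edge")
})

test_that("edge TSV round-trips and rejects bad files", {
  g <- tiny_graph()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_graph_file(g, f, format = "edge_tsv")
  g2 <- read_graph_file(f)
  expect_identical(g2$nodes, g$nodes)
  expect_identical(g2$edges, g$edges)

  writeLines(c("source\tsource_type\tedge_type\tsign\ttarget\ttarget_type",
               "A\tprotein\texpression_regulation\tup\tB\tprotein"), f)
  expect_error(read_graph_file(f), "gene node")
  writeLines(c("source\tsource_type\tedge_type\tsign\ttarget\ttarget_type",
               "A\tprotein\tbinds\tup\tB\tprotein"), f)
  expect_error(read_graph_file(f), "allowed")
  writeLines("bad header", f)
  expect_error(read_graph_file(f), "header")
})

test_that("SIF round-trips via its node-type sidecar", {
  g <- tiny_graph()
  f <- withr::local_tempfile(fileext = ".sif")
  write_graph_file(g, f, format = "sif")
  expect_true(file.exists(paste0(f, ".nodes.tsv")))
  g2 <- read_graph_file(f)
  expect_identical(g2$nodes, g$nodes)
  expect_identical(g2$edges, g$edges)
})

test_that("GraphML round-trips with attributes intact", {
  sim <- simulate_knowledge_graph(graph_sim_config(
    n_marker_proteins = 3, n_enzymes = 2, n_intermediates = 2,
    planted_paths = list(c("M1", "E1", "T4"), c("M2", "E2", "T1")),
    random_edge_prob = 0.2, seed = 17))
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graph_file(sim$graph, f, format = "graphml")
  g2 <- read_graph_file(f)
  expect_identical(g2$nodes, sim$graph$nodes)
  expect_identical(g2$edges, sim$graph$edges)
})

test_that("simulated graphs round-trip through every dialect", {
  sim <- simulate_knowledge_graph(graph_sim_config(
    n_marker_proteins = 4, n_enzymes = 3, n_intermediates = 2,
    n_noise_nodes = 2, random_edge_prob = 0.15, seed = 23))
  for (fmt in c("edge_tsv", "sif", "graphml")) {
    f <- withr::local_tempfile(
      fileext = switch(fmt, edge_tsv = ".tsv", sif = ".sif", ".graphml"))
    write_graph_file(sim$graph, f, format = fmt)
    g2 <- read_graph_file(f)
    expect_identical(g2$nodes, sim$graph$nodes, info = fmt)
    expect_identical(g2$edges, sim$graph$edges, info = fmt)
  }
})

test_that("isolated nodes survive round trips in every dialect", {
  g <- knowledge_graph(
    data.frame(id = c("A", "B", "lonely", "gX"),
               type = c("protein", "protein", "protein", "gene")),
    data.frame(source = "A", target = "B", type = "ppi"))
  for (fmt in c("edge_tsv", "sif", "graphml")) {
    f <- withr::local_tempfile(
      fileext = switch(fmt, edge_tsv = ".tsv", sif = ".sif", ".graphml"))
    write_graph_file(g, f, format = fmt)
    g2 <- read_graph_file(f)
    expect_identical(g2$nodes, g$nodes, info = fmt)
    expect_identical(g2$edges, g$edges, info = fmt)
  }
})

test_that("subgraph_between returns exactly the path-spanning induced graph", {
  g <- tiny_graph()
  # no path within length 1 from A to E
  empty <- suppressWarnings(subgraph_between(g, "A", "E", max_len = 1))
  expect_equal(nrow(empty$nodes), 0)
  # A -> B -> gE -> E requires length 3
  sub <- subgraph_between(g, "A", "E", max_len = 3)
  expect_setequal(sub$nodes$id, c("A", "B", "gE", "E"))
  expect_equal(nrow(sub$edges), 4)
  expect_warning(subgraph_between(g, "Z", "E", max_len = 2), "absent")
})

test_that("subgraph_between equals a brute-force path-union oracle", {
  for (seed in c(1, 2, 3)) {
    g <- random_typed_graph(10, 0.12, seed)
    prot <- g$nodes$id[g$nodes$type == "protein"]
    if (length(prot) < 4) next
    sources <- prot[1:2]; targets <- prot[3:4]
    for (max_len in c(2, 3)) {
      cand <- oracle_all_simple_paths(g, sources, targets, max_len)
      expected_nodes <- sort(unique(unlist(lapply(cand, `[[`, "nodes"))))
      sub <- suppressWarnings(subgraph_between(g, sources, targets, max_len))
      expect_equal(sub$nodes$id, expected_nodes)
      exp_edges <- g$edges[g$edges$source %in% expected_nodes &
                           g$edges$target %in% expected_nodes, ]
      rownames(exp_edges) <- NULL
      expect_equal(sub$edges, exp_edges)
    }
  }
})
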