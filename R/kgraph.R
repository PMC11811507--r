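EDGE_TYPES <- c("ppi", "activity_regulation", "degradation_regulation",
                "transport_regulation", "proteolysis_regulation",
                "catalysis_regulation", "expression_regulation", "encodes")
NODE_TYPES <- c("protein", "gene")
EDGE_SIGNS <- c("up", "down", "unknown")

# protein-level regulation: every edge kind acting on a protein node
PROTEIN_LEVEL_TYPES <- c("ppi", "activity_regulation", "degradation_regulation",
                         "transport_regulation", "proteolysis_regulation",
                         "catalysis_regulation")

#' Typed molecular-interaction graph
#'
#' Directed multigraph over protein and gene nodes with a fixed edge-type
#' vocabulary: `ppi` (protein-protein interaction, stored as two directed
#' edges), five protein-level regulation kinds (`activity_regulation`,
#' `degradation_regulation`, `transport_regulation`, `proteolysis_regulation`,
#' `catalysis_regulation`), `expression_regulation` (protein -> gene) and
#' `encodes` (gene -> protein). Each edge carries a sign
#' (`up`/`down`/`unknown`).
#'
#' Structural invariants enforced at construction: edge endpoints exist;
#' `expression_regulation` targets gene nodes only; `encodes` runs gene ->
#' protein only; `ppi` connects proteins only; no self-loops; no duplicated
#' (source, target, type) triple.
#'
#' @param nodes data.frame with columns `id`, `type`.
#' @param edges data.frame with columns `source`, `target`, `type` and
#'   optionally `sign` (default `"unknown"`).
#' @return object of class `knowledge_graph` (list of the two validated,
#'   lexicographically sorted data.frames).
#' @export
knowledge_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("id", "type") %in% names(nodes)))
    stop("nodes need `id` and `type` columns", call. = FALSE)
  if (nrow(edges) == 0L)
    edges <- data.frame(source = character(), target = character(),
                        type = character(), sign = character(),
                        stringsAsFactors = FALSE)
  if (!all(c("source", "target", "type") %in% names(edges)))
    stop("edges need `source`, `target`, `type` columns", call. = FALSE)
  if (is.null(edges$sign)) edges$sign <- rep("unknown", nrow(edges))
  edges$sign[is.na(edges$sign) | edges$sign == ""] <- "unknown"

  if (anyDuplicated(nodes$id))
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1], call. = FALSE)
  bad <- !nodes$type %in% NODE_TYPES
  if (any(bad))
    stop("unknown node type '", nodes$type[bad][1], "'; allowed: ",
         paste(NODE_TYPES, collapse = ", "), call. = FALSE)
  bad <- !edges$type %in% EDGE_TYPES
  if (any(bad))
    stop("unknown edge type '", edges$type[bad][1], "'; allowed: ",
         paste(EDGE_TYPES, collapse = ", "), call. = FALSE)
  bad <- !edges$sign %in% EDGE_SIGNS
  if (any(bad))
    stop("unknown edge sign '", edges$sign[bad][1], "'", call. = FALSE)

  ntype <- stats::setNames(nodes$type, nodes$id)
  dangling <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(dangling))
    stop("edge endpoint not declared as a node: ", dangling[1], call. = FALSE)
  if (any(edges$source == edges$target))
    stop("self-loops are not allowed (", edges$source[edges$source == edges$target][1],
         ")", call. = FALSE)
  viol <- edges$type == "expression_regulation" & ntype[edges$target] != "gene"
  if (any(viol))
    stop("expression_regulation must target a gene node (",
         edges$source[viol][1], " -> ", edges$target[viol][1], ")", call. = FALSE)
  viol <- edges$type == "encodes" &
    (ntype[edges$source] != "gene" | ntype[edges$target] != "protein")
  if (any(viol))
    stop("encodes must run gene -> protein (",
         edges$source[viol][1], " -> ", edges$target[viol][1], ")", call. = FALSE)
  viol <- edges$type == "ppi" &
    (ntype[edges$source] != "protein" | ntype[edges$target] != "protein")
  if (any(viol))
    stop("ppi must connect two proteins (",
         edges$source[viol][1], " -> ", edges$target[viol][1], ")", call. = FALSE)
  key <- paste(edges$source, edges$target, edges$type, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate edge (source, target, type): ",
         gsub("\r", " ", key[duplicated(key)][1]), call. = FALSE)

  nodes <- nodes[order(nodes$id), c("id", "type"), drop = FALSE]
  edges <- edges[order(edges$source, edges$target, edges$type),
                 c("source", "target", "type", "sign"), drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("Knowledge graph:", nrow(x$nodes), "nodes (",
      sum(x$nodes$type == "protein"), "proteins,",
      sum(x$nodes$type == "gene"), "genes ),",
      nrow(x$edges), "directed edges\n")
  if (nrow(x$edges)) {
    tab <- table(x$edges$type)
    cat("Edge types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a typed interaction graph
#'
#' Three dialects are supported. `edge_tsv`: header line then
#' `source<TAB>source_type<TAB>edge_type<TAB>sign<TAB>target<TAB>target_type`;
#' isolated nodes appear as two-field `id<TAB>type` lines.
#' `sif`: `source<TAB>relation<TAB>target` where relation is
#' `edge_type` or `edge_type(sign)` and a bare id on a line declares an
#' isolated node; node types are taken from a
#' `<path>.nodes.tsv` sidecar (written by [write_graph_file()]) when present,
#' otherwise inferred from edge-type constraints (targets of
#' `expression_regulation` and sources of `encodes` are genes, the rest
#' proteins). `graphml`: igraph GraphML with `type` node/edge attributes and
#' a `sign` edge attribute.
#'
#' @param path file path.
#' @param format `"edge_tsv"`, `"sif"` or `"graphml"` (default from extension:
#'   `.tsv`, `.sif`, `.graphml`).
#' @return a validated [knowledge_graph]. Invariant violations are reported
#'   with the offending line where the dialect is line-oriented.
#' @export
read_graph_file <- function(path, format = c("auto", "edge_tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "edge_tsv", txt = "edge_tsv", sif = "sif",
                     graphml = "graphml", xml = "graphml",
                     stop("cannot guess graph format from '.", ext, "'", call. = FALSE))
  }
  switch(format,
    edge_tsv = read_graph_edge_tsv(path),
    sif = read_graph_sif(path),
    graphml = read_graph_graphml(path))
}

read_graph_edge_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty graph file: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  expected <- c("source", "source_type", "edge_type", "sign", "target", "target_type")
  if (!identical(header, expected))
    stop("bad edge TSV header; expected: ", paste(expected, collapse = ", "),
         call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(!lengths(parts) %in% c(2L, 6L))
  if (length(bad))
    stop("line ", bad[1] + 1L,
         ": expected 6 tab-separated fields (edge) or 2 (isolated node)",
         call. = FALSE)
  isolated <- parts[lengths(parts) == 2L]
  parts <- parts[lengths(parts) == 6L]
  f <- function(i) vapply(parts, `[[`, "", i)
  edges <- data.frame(source = f(1), target = f(5), type = f(3), sign = f(4),
                      stringsAsFactors = FALSE)
  nodes <- unique(data.frame(
    id = c(f(1), f(5), vapply(isolated, `[[`, "", 1L)),
    type = c(f(2), f(6), vapply(isolated, `[[`, "", 2L)),
    stringsAsFactors = FALSE))
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup))
    stop("node '", dup[1], "' declared with conflicting types", call. = FALSE)
  knowledge_graph(nodes, edges)
}

read_graph_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(!lengths(parts) %in% c(1L, 3L))
  if (length(bad))
    stop("SIF line ", bad[1], ": expected source<TAB>relation<TAB>target",
         " or a bare node id", call. = FALSE)
  lone <- unlist(parts[lengths(parts) == 1L])
  parts <- parts[lengths(parts) == 3L]
  rel <- vapply(parts, `[[`, "", 2L)
  sign <- ifelse(grepl("\\(", rel), sub("^.*\\(([^)]*)\\)$", "\\1", rel), "unknown")
  type <- sub("\\(.*$", "", rel)
  edges <- data.frame(source = vapply(parts, `[[`, "", 1L),
                      target = vapply(parts, `[[`, "", 3L),
                      type = type, sign = sign, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".nodes.tsv")
  ids <- unique(c(edges$source, edges$target, lone))
  if (file.exists(sidecar)) {
    nt <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    nodes <- data.frame(id = nt$id, type = nt$type, stringsAsFactors = FALSE)
    ids <- union(ids, nodes$id)
    missing <- setdiff(ids, nodes$id)
    if (length(missing))
      nodes <- rbind(nodes, data.frame(id = missing, type = "protein",
                                       stringsAsFactors = FALSE))
  } else {
    genes <- unique(c(edges$target[edges$type == "expression_regulation"],
                      edges$source[edges$type == "encodes"]))
    nodes <- data.frame(id = ids,
                        type = ifelse(ids %in% genes, "gene", "protein"),
                        stringsAsFactors = FALSE)
  }
  knowledge_graph(nodes, edges)
}

read_graph_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name, type = igraph::V(g)$type,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(source = el[, 1], target = el[, 2],
                      type = igraph::E(g)$type,
                      sign = if ("sign" %in% igraph::edge_attr_names(g))
                        igraph::E(g)$sign else "unknown",
                      stringsAsFactors = FALSE)
  knowledge_graph(nodes, edges)
}

#' Write a typed interaction graph
#'
#' Deterministic output: edges sorted lexicographically by (source, target,
#' type). The SIF dialect cannot carry node types, so it writes a
#' `<path>.nodes.tsv` sidecar (`id<TAB>type`); signs other than `unknown`
#' are encoded in the relation as `edge_type(sign)`.
#'
#' @param graph a [knowledge_graph].
#' @param path output path.
#' @param format `"edge_tsv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path,
                             format = c("edge_tsv", "sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "knowledge_graph"))
  e <- graph$edges
  ntype <- stats::setNames(graph$nodes$type, graph$nodes$id)
  isolated <- setdiff(graph$nodes$id, c(e$source, e$target))
  if (format == "edge_tsv") {
    lines <- c(
      "source\tsource_type\tedge_type\tsign\ttarget\ttarget_type",
      if (nrow(e)) paste(e$source, ntype[e$source], e$type, e$sign,
                         e$target, ntype[e$target], sep = "\t"),
      if (length(isolated)) paste(isolated, ntype[isolated], sep = "\t")
    )
    writeLines(lines, path)
  } else if (format == "sif") {
    rel <- ifelse(e$sign == "unknown", e$type, paste0(e$type, "(", e$sign, ")"))
    writeLines(c(if (nrow(e)) paste(e$source, rel, e$target, sep = "\t"),
                 isolated), path)
    writeLines(c("id\ttype", paste(graph$nodes$id, graph$nodes$type, sep = "\t")),
               paste0(path, ".nodes.tsv"))
  } else {
    g <- as_igraph(graph)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a knowledge graph to an igraph object
#'
#' Node `type` and edge `type`/`sign` become igraph attributes; parallel
#' edges of different types are preserved.
#'
#' @param graph a [knowledge_graph].
#' @return an igraph directed graph.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "knowledge_graph"))
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = graph$nodes)
}

#' Subgraph spanned by bounded simple paths between node sets
#'
#' Returns the knowledge graph induced on all nodes that lie on at least one
#' simple directed path of length at most `max_len` edges from any source to
#' any target (induced: every edge of the original graph between retained
#' nodes is kept). May be empty.
#'
#' @param graph a [knowledge_graph].
#' @param sources,targets character vectors of node ids; ids absent from the
#'   graph are ignored with a warning.
#' @param max_len maximum path length in edges (>= 1).
#' @return a [knowledge_graph].
#' @export
subgraph_between <- function(graph, sources, targets, max_len) {
  stopifnot(inherits(graph, "knowledge_graph"), max_len >= 1)
  missing <- setdiff(c(sources, targets), graph$nodes$id)
  if (length(missing))
    warning("ids absent from graph: ", paste(missing, collapse = ", "),
            call. = FALSE)
  sources <- intersect(sources, graph$nodes$id)
  targets <- intersect(targets, graph$nodes$id)
  keep <- character()
  if (length(sources) && length(targets) && nrow(graph$edges)) {
    # simple-path node search on the type-collapsed digraph
    g <- igraph::graph_from_data_frame(
      unique(graph$edges[, c("source", "target")]),
      directed = TRUE, vertices = graph$nodes$id)
    for (s in sources) {
      paths <- igraph::all_simple_paths(g, from = s, to = targets,
                                        mode = "out", cutoff = max_len)
      for (p in paths) keep <- union(keep, names(p))
    }
  }
  nodes <- graph$nodes[graph$nodes$id %in% keep, , drop = FALSE]
  edges <- graph$edges[graph$edges$source %in% keep &
                       graph$edges$target %in% keep, , drop = FALSE]
  knowledge_graph(nodes, edges)
}
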