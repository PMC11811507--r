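#' Enumerate regulatory pathways matching a template
#'
#' Depth-first enumeration of all distinct simple directed paths from any
#' source (marker protein) to any target (enzyme protein) whose edge-type and
#' node-type sequence matches the template. Two paths are distinct iff their
#' (node sequence, edge-type sequence) pairs differ, so parallel edges of
#' different types between the same nodes yield distinct paths. Edge signs
#' are carried along but not constrained. A path never revisits a node
#' (which also prevents traversing both stored directions of one `ppi`
#' pair). Output is sorted lexicographically by (node chain, edge-type
#' chain) for reproducible diffs.
#'
#' @param graph a [knowledge_graph].
#' @param template a [path_template].
#' @param sources character vector of marker protein ids; ids missing from
#'   the graph are dropped with a warning, not an error.
#' @param targets character vector of enzyme protein ids; same policy.
#' @return data.frame of class `regulatory_paths`, one row per path:
#'   `template`, `marker`, `enzyme`, `length`, `nodes` (ids joined by `->`),
#'   `edge_types` and `signs` (joined by `;`).
#' @export
enumerate_template_paths <- function(graph, template, sources, targets) {
  stopifnot(inherits(graph, "knowledge_graph"),
            inherits(template, "path_template"))
  all_ids <- graph$nodes$id
  missing <- setdiff(c(sources, targets), all_ids)
  if (length(missing))
    warning("ids absent from graph: ", paste(unique(missing), collapse = ", "),
            call. = FALSE)
  sources <- sort(intersect(unique(sources), all_ids))
  targets <- intersect(unique(targets), all_ids)
  ntype <- stats::setNames(graph$nodes$type, all_ids)
  sources <- sources[ntype[sources] == "protein"]
  targets <- targets[ntype[targets] == "protein"]

  out <- empty_paths()
  if (!length(sources) || !length(targets) || !nrow(graph$edges))
    return(out)

  edges_by_source <- split(graph$edges, graph$edges$source)
  target_set <- targets
  step_seqs <- template_step_sequences(template)

  acc <- list()
  walk <- function(node, steps, depth, nodes, etypes, signs) {
    if (depth > length(steps)) {
      if (node %in% target_set)
        acc[[length(acc) + 1L]] <<- list(nodes = nodes, etypes = etypes,
                                         signs = signs)
      return(invisible())
    }
    step <- steps[[depth]]
    out_edges <- edges_by_source[[node]]
    if (is.null(out_edges)) return(invisible())
    ok <- out_edges$type %in% step$edge_types &
      ntype[out_edges$target] == step$node_type &
      !(out_edges$target %in% nodes)
    if (!any(ok)) return(invisible())
    out_edges <- out_edges[ok, , drop = FALSE]
    # prune: the final step must land on a target
    if (depth == length(steps))
      out_edges <- out_edges[out_edges$target %in% target_set, , drop = FALSE]
    for (i in seq_len(nrow(out_edges))) {
      walk(out_edges$target[i], steps, depth + 1L,
           c(nodes, out_edges$target[i]),
           c(etypes, out_edges$type[i]),
           c(signs, out_edges$sign[i]))
    }
  }
  for (steps in step_seqs)
    for (s in sources)
      walk(s, steps, 1L, s, character(), character())

  if (!length(acc)) return(out)
  res <- data.frame(
    template = template$id,
    marker = vapply(acc, function(p) p$nodes[1], ""),
    enzyme = vapply(acc, function(p) p$nodes[length(p$nodes)], ""),
    length = vapply(acc, function(p) length(p$etypes), 0L),
    nodes = vapply(acc, function(p) paste(p$nodes, collapse = "->"), ""),
    edge_types = vapply(acc, function(p) paste(p$etypes, collapse = ";"), ""),
    signs = vapply(acc, function(p) paste(p$signs, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  # distinct = (node sequence, edge-type sequence); overlapping repeat
  # ranges could revisit the same concrete path
  res <- res[!duplicated(paste(res$nodes, res$edge_types, sep = "\r")), ,
             drop = FALSE]
  res <- res[order(res$nodes, res$edge_types), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("regulatory_paths", "data.frame")
  res
}

empty_paths <- function() {
  res <- data.frame(template = character(), marker = character(),
                    enzyme = character(), length = integer(),
                    nodes = character(), edge_types = character(),
                    signs = character(), stringsAsFactors = FALSE)
  class(res) <- c("regulatory_paths", "data.frame")
  res
}

#' Enumerate pathways for several templates at once
#'
#' @param graph a [knowledge_graph].
#' @param templates named list of [path_template] objects
#'   (default [default_templates()]).
#' @param sources,targets as in [enumerate_template_paths()].
#' @return a `regulatory_paths` data.frame, rows from all templates, sorted
#'   by (template, nodes, edge_types).
#' @export
enumerate_all_templates <- function(graph, sources, targets,
                                    templates = default_templates()) {
  parts <- lapply(templates, function(t)
    suppressWarnings(enumerate_template_paths(graph, t, sources, targets)))
  # warn once about missing ids
  missing <- setdiff(c(sources, targets), graph$nodes$id)
  if (length(missing))
    warning("ids absent from graph: ", paste(unique(missing), collapse = ", "),
            call. = FALSE)
  res <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  res <- res[order(res$template, res$nodes, res$edge_types), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("regulatory_paths", "data.frame")
  res
}

#' Count pathways per (marker, enzyme) with group and class margins
#'
#' Aggregates an enumerated path list into the marker x enzyme count matrix
#' behind the study's histograms: each marker is annotated with its
#' disease-marker group (`<A>_specific` / `<B>_specific` / `shared`) from a
#' [partition_markers()] result, each enzyme with its metabolism class from
#' an enzyme map. Markers or enzymes that cannot be annotated are counted
#' under `"unassigned"` with a warning.
#'
#' @param paths a `regulatory_paths` data.frame.
#' @param partition a `marker_partition` (see [partition_markers()]), or
#'   `NULL` to skip marker-group annotation.
#' @param enzyme_map an `enzyme_map` data.frame (see [read_enzyme_map()]), or
#'   `NULL` to skip enzyme-class annotation.
#' @param dedupe `"paths"` (default; count every distinct path) or `"pairs"`
#'   (count each distinct (marker, enzyme) pair once per template).
#' @return object of class `pathway_counts`: list with `counts` (marker x
#'   enzyme integer matrix), `marker_group` and `enzyme_class` (named
#'   character vectors), `paths` (the possibly deduplicated path table).
#'   The matrix total equals `nrow(paths)` under `dedupe = "paths"`.
#' @export
count_paths <- function(paths, partition = NULL, enzyme_map = NULL,
                        dedupe = c("paths", "pairs")) {
  dedupe <- match.arg(dedupe)
  stopifnot(is.data.frame(paths))
  if (dedupe == "pairs")
    paths <- paths[!duplicated(paths[c("template", "marker", "enzyme")]), ,
                   drop = FALSE]
  markers <- sort(unique(paths$marker))
  enzymes <- sort(unique(paths$enzyme))
  counts <- matrix(0L, length(markers), length(enzymes),
                   dimnames = list(markers, enzymes))
  if (nrow(paths)) {
    tab <- table(factor(paths$marker, levels = markers),
                 factor(paths$enzyme, levels = enzymes))
    counts[] <- as.integer(tab)
  }

  marker_group <- stats::setNames(rep("unassigned", length(markers)), markers)
  if (!is.null(partition)) {
    stopifnot(inherits(partition, "marker_partition"))
    ga <- partition$labels[1]; gb <- partition$labels[2]
    marker_group[markers %in% partition$A_only] <- paste0(ga, "_specific")
    marker_group[markers %in% partition$B_only] <- paste0(gb, "_specific")
    marker_group[markers %in% partition$shared] <- "shared"
  }
  enzyme_class <- stats::setNames(rep("unassigned", length(enzymes)), enzymes)
  if (!is.null(enzyme_map)) {
    cls <- unique(enzyme_map[c("enzyme_protein_id", "enzyme_class")])
    hit <- match(enzymes, cls$enzyme_protein_id)
    enzyme_class[!is.na(hit)] <- cls$enzyme_class[hit[!is.na(hit)]]
  }
  if (any(marker_group == "unassigned") && !is.null(partition))
    warning("markers not in any partition group counted as 'unassigned': ",
            paste(markers[marker_group == "unassigned"], collapse = ", "),
            call. = FALSE)
  if (any(enzyme_class == "unassigned") && !is.null(enzyme_map))
    warning("enzymes without a class counted as 'unassigned': ",
            paste(enzymes[enzyme_class == "unassigned"], collapse = ", "),
            call. = FALSE)

  structure(list(counts = counts, marker_group = marker_group,
                 enzyme_class = enzyme_class, paths = paths,
                 dedupe = dedupe),
            class = "pathway_counts")
}

#' @export
print.pathway_counts <- function(x, ...) {
  cat("Pathway counts:", sum(x$counts), "paths,",
      nrow(x$counts), "markers x", ncol(x$counts), "enzymes",
      sprintf("(dedupe = %s)\n", x$dedupe))
  invisible(x)
}

#' Write an enumerated path list as TSV
#'
#' One row per path: template, marker, enzyme, length, node chain, edge-type
#' chain, sign chain.
#'
#' @param paths a `regulatory_paths` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_paths <- function(paths, path) {
  utils::write.table(paths, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
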