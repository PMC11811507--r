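#' Configuration for a simulated knowledge graph
#'
#' Describes a typed interaction graph with named marker proteins (`M1`...),
#' enzyme proteins (`E1`...) each with an encoding gene (`gE1`...),
#' dedicated intermediate proteins (`I1`...), optional noise proteins
#' (`N1`...), a set of planted template-conforming paths, and Erdos-Renyi
#' noise edges.
#'
#' @param n_marker_proteins,n_enzymes,n_intermediates,n_noise_nodes node
#'   counts per role.
#' @param planted_paths list of length-3 character vectors / lists
#'   `(marker id, enzyme id, template id)`; template ids must exist in
#'   `templates`.
#' @param random_edge_prob probability in [0, 1] of a noise edge for each
#'   ordered protein pair (type drawn uniformly from the protein-level
#'   kinds) and each (protein, enzyme gene) pair (`expression_regulation`).
#'   Noise never duplicates a planted (source, target, type) triple and
#'   never adds self-loops.
#' @param templates named list of templates the planted ids refer to
#'   (default [default_templates()]).
#' @param seed integer seed.
#' @return list of class `graph_sim_config`.
#' @export
graph_sim_config <- function(n_marker_proteins = 3L, n_enzymes = 2L,
                             n_intermediates = 2L, n_noise_nodes = 0L,
                             planted_paths = list(),
                             random_edge_prob = 0,
                             templates = default_templates(),
                             seed = 1L) {
  if (random_edge_prob < 0 || random_edge_prob > 1)
    stop("random_edge_prob must be in [0, 1]", call. = FALSE)
  markers <- sprintf("M%d", seq_len(n_marker_proteins))
  enzymes <- sprintf("E%d", seq_len(n_enzymes))
  for (p in planted_paths) {
    p <- as.character(unlist(p))
    if (length(p) != 3L)
      stop("planted path must be (marker, enzyme, template)", call. = FALSE)
    if (!p[1] %in% markers) stop("unknown planted marker: ", p[1], call. = FALSE)
    if (!p[2] %in% enzymes) stop("unknown planted enzyme: ", p[2], call. = FALSE)
    if (!p[3] %in% names(templates))
      stop("unknown planted template id: ", p[3], call. = FALSE)
  }
  structure(
    list(n_marker_proteins = as.integer(n_marker_proteins),
         n_enzymes = as.integer(n_enzymes),
         n_intermediates = as.integer(n_intermediates),
         n_noise_nodes = as.integer(n_noise_nodes),
         planted_paths = planted_paths,
         random_edge_prob = random_edge_prob,
         templates = templates,
         seed = as.integer(seed)),
    class = "graph_sim_config"
  )
}

# core builder; assumes the RNG is already seeded by the caller.
# enzyme genes are named g<enzyme>; every enzyme gets an encodes edge.
build_planted_graph <- function(markers, enzymes, inters, noise,
                                planted_paths, random_edge_prob, templates) {
  genes <- sprintf("g%s", enzymes)
  nodes <- data.frame(
    id = c(markers, enzymes, inters, noise, genes),
    type = c(rep("protein", length(markers) + length(enzymes) +
                   length(inters) + length(noise)),
             rep("gene", length(genes))),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(nodes$id))
    stop("marker/enzyme/intermediate ids collide: ",
         nodes$id[duplicated(nodes$id)][1], call. = FALSE)

  edges <- data.frame(source = genes, target = enzymes,
                      type = rep("encodes", length(genes)),
                      sign = rep("unknown", length(genes)),
                      stringsAsFactors = FALSE)
  add_edge <- function(s, t, ty, sg = "unknown")
    edges <<- rbind(edges, data.frame(source = s, target = t, type = ty,
                                      sign = sg, stringsAsFactors = FALSE))
  pl <- PROTEIN_LEVEL_TYPES
  next_inter <- 0L
  take_inter <- function() {
    if (!length(inters))
      stop("planted mediated path needs >= 1 intermediate", call. = FALSE)
    next_inter <<- next_inter %% length(inters) + 1L
    inters[next_inter]
  }
  planted <- data.frame(marker = character(), enzyme = character(),
                        template = character(), stringsAsFactors = FALSE)
  for (p in planted_paths) {
    p <- as.character(unlist(p))
    m <- p[1]; e <- p[2]; tid <- p[3]
    g <- paste0("g", e)
    switch(tid,
      T1 = add_edge(m, e, sample(pl, 1L)),
      T2 = add_edge(m, g, "expression_regulation",
                    sample(c("up", "down"), 1L)),
      T3 = { i <- take_inter()
             add_edge(m, i, sample(pl, 1L))
             add_edge(i, e, sample(pl, 1L)) },
      T4 = { i <- take_inter()
             add_edge(m, i, sample(pl, 1L))
             add_edge(i, g, "expression_regulation",
                      sample(c("up", "down"), 1L)) },
      stop("planting not implemented for template '", tid, "'", call. = FALSE)
    )
    planted <- rbind(planted, data.frame(marker = m, enzyme = e,
                                         template = tid,
                                         stringsAsFactors = FALSE))
  }
  # two planted paths may share a step
  edges <- edges[!duplicated(paste(edges$source, edges$target, edges$type)), ,
                 drop = FALSE]

  if (random_edge_prob > 0) {
    proteins <- c(markers, enzymes, inters, noise)
    pairs <- expand.grid(source = proteins, target = proteins,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
    hit <- stats::runif(nrow(pairs)) < random_edge_prob
    if (any(hit)) {
      np <- pairs[hit, , drop = FALSE]
      np$type <- sample(pl, nrow(np), replace = TRUE)
      np$sign <- "unknown"
      edges <- rbind(edges, np)
    }
    gpairs <- expand.grid(source = proteins, target = genes,
                          stringsAsFactors = FALSE)
    hit <- stats::runif(nrow(gpairs)) < random_edge_prob
    if (any(hit)) {
      np <- gpairs[hit, , drop = FALSE]
      np$type <- "expression_regulation"
      np$sign <- sample(c("up", "down", "unknown"), nrow(np), replace = TRUE)
      edges <- rbind(edges, np)
    }
    edges <- edges[!duplicated(paste(edges$source, edges$target, edges$type)), ,
                   drop = FALSE]
  }

  # ppi is undirected in nature: store both directions
  is_ppi <- edges$type == "ppi"
  if (any(is_ppi)) {
    rev <- edges[is_ppi, , drop = FALSE]
    tmp <- rev$source; rev$source <- rev$target; rev$target <- tmp
    edges <- rbind(edges, rev)
    edges <- edges[!duplicated(paste(edges$source, edges$target, edges$type)), ,
                   drop = FALSE]
  }

  list(graph = knowledge_graph(nodes, edges),
       markers = markers, enzymes = enzymes, planted = planted)
}

#' Simulate a typed knowledge graph with planted template paths
#'
#' Builds the node roster from the config, plants each requested path as an
#' exact instance of its template (one fresh intermediate is consumed per
#' planted T3/T4 path, reused cyclically), gives every enzyme an encoding
#' gene with an `encodes` edge, then sprinkles noise edges at
#' `random_edge_prob`. Planted edges are never duplicated by noise, so
#' planted path counts are exact in noise-free graphs. Reproducible given
#' the seed.
#'
#' @param config a [graph_sim_config()].
#' @return list with `graph` (a [knowledge_graph]), `markers`, `enzymes`
#'   (character vectors), and `planted` (data.frame of planted
#'   marker/enzyme/template triples).
#' @export
simulate_knowledge_graph <- function(config) {
  stopifnot(inherits(config, "graph_sim_config"))
  with_local_seed(config$seed, {
    build_planted_graph(
      markers = sprintf("M%d", seq_len(config$n_marker_proteins)),
      enzymes = sprintf("E%d", seq_len(config$n_enzymes)),
      inters = if (config$n_intermediates)
        sprintf("I%d", seq_len(config$n_intermediates)) else character(),
      noise = if (config$n_noise_nodes)
        sprintf("N%d", seq_len(config$n_noise_nodes)) else character(),
      planted_paths = config$planted_paths,
      random_edge_prob = config$random_edge_prob,
      templates = config$templates
    )
  })
}

#' Simulate a knowledge graph over named markers and enzymes
#'
#' Study-scale variant of [simulate_knowledge_graph()] that takes real gene
#' symbols: plants `n_paths` template paths from randomly chosen markers to
#' randomly chosen enzymes (templates drawn uniformly), with generated
#' intermediate proteins and optional noise edges.
#'
#' @param markers,enzymes character vectors of protein ids (disjoint).
#' @param n_paths number of planted paths.
#' @param n_intermediates intermediate proteins available to mediated
#'   templates (named `X1`...).
#' @param random_edge_prob noise edge probability as in
#'   [graph_sim_config()].
#' @param templates named list of templates to draw from.
#' @param seed integer seed.
#' @return as [simulate_knowledge_graph()].
#' @export
simulate_marker_enzyme_graph <- function(markers, enzymes, n_paths = 50L,
                                         n_intermediates = 10L,
                                         random_edge_prob = 0,
                                         templates = default_templates(),
                                         seed = 1L) {
  markers <- unique(as.character(markers))
  enzymes <- unique(as.character(enzymes))
  if (length(intersect(markers, enzymes)))
    stop("markers and enzymes must be disjoint", call. = FALSE)
  with_local_seed(seed, {
    planted <- lapply(seq_len(n_paths), function(i)
      c(sample(markers, 1L), sample(enzymes, 1L),
        sample(names(templates), 1L)))
    build_planted_graph(
      markers = markers, enzymes = enzymes,
      inters = if (n_intermediates)
        sprintf("X%d", seq_len(n_intermediates)) else character(),
      noise = character(),
      planted_paths = planted,
      random_edge_prob = random_edge_prob,
      templates = templates
    )
  })
}
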