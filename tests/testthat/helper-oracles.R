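# Independent oracles used across the suite. These deliberately use brute
# force (full enumeration) and never call the code paths they check.

# two-sided Mann-Whitney p by full enumeration of group assignments,
# doubling convention (twice the smaller tail, capped at 1)
perm_mw_pvalue <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  ustat <- function(xi, yi) sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  u_obs <- ustat(x, y)
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2, function(i) ustat(pooled[i], pooled[-i]))
  min(1, 2 * min(mean(us <= u_obs + 1e-12), mean(us >= u_obs - 1e-12)))
}

# exact KS p by full enumeration: P(D* >= D_obs)
perm_ks_pvalue <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  dstat <- function(xi, yi) {
    z <- sort(unique(c(xi, yi)))
    max(abs(stats::ecdf(xi)(z) - stats::ecdf(yi)(z)))
  }
  d_obs <- dstat(x, y)
  idx <- utils::combn(nx + ny, nx)
  ds <- apply(idx, 2, function(i) dstat(pooled[i], pooled[-i]))
  mean(ds >= d_obs - 1e-12)
}

ks_d_stat <- function(x, y) {
  z <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(z) - stats::ecdf(y)(z)))
}

# BH step-up by the direct formula with an explicit monotonicity pass
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- brute-force template path oracle ------------------------------------

# does a concrete (edge type, node type) sequence match the template's
# segments?  independent recursive matcher over repeat ranges
oracle_template_match <- function(template, edge_types, node_types) {
  match_seg <- function(si, pos) {
    if (si > length(template$segments))
      return(pos == length(edge_types) + 1L)
    s <- template$segments[[si]]
    for (reps in s$min:s$max) {
      ok <- TRUE
      if (reps > 0) {
        span <- pos + seq_len(reps) - 1L
        if (max(span) > length(edge_types)) { ok <- FALSE }
        else {
          for (k in span) {
            if (!(edge_types[k] %in% s$edge_types) ||
                node_types[k] != s$node_type) { ok <- FALSE; break }
          }
        }
      }
      if (ok && match_seg(si + 1L, pos + reps)) return(TRUE)
    }
    FALSE
  }
  match_seg(1L, 1L)
}

# all simple paths from sources to targets up to max_len edges, expanded
# over parallel edges; returns list of list(nodes, etypes)
oracle_all_simple_paths <- function(graph, sources, targets, max_len) {
  edges <- graph$edges
  out <- list()
  recurse <- function(node, nodes, etypes) {
    if (length(etypes) > 0 && node %in% targets)
      out[[length(out) + 1L]] <<- list(nodes = nodes, etypes = etypes)
    if (length(etypes) == max_len) return(invisible())
    nxt <- edges[edges$source == node & !(edges$target %in% nodes), ,
                 drop = FALSE]
    for (i in seq_len(nrow(nxt)))
      recurse(nxt$target[i], c(nodes, nxt$target[i]), c(etypes, nxt$type[i]))
  }
  for (s in intersect(sources, graph$nodes$id)) recurse(s, s, character())
  out
}

# brute-force equivalent of enumerate_template_paths: all simple paths up
# to the template's maximum length, filtered by the independent matcher
oracle_template_paths <- function(graph, template, sources, targets) {
  max_len <- sum(vapply(template$segments, `[[`, 0L, "max"))
  ntype <- stats::setNames(graph$nodes$type, graph$nodes$id)
  cand <- oracle_all_simple_paths(graph, sources, targets, max_len)
  keep <- Filter(function(p) {
    node_types <- unname(ntype[p$nodes[-1]])
    ntype[p$nodes[1]] == "protein" &&
      oracle_template_match(template, p$etypes, node_types)
  }, cand)
  if (!length(keep)) return(character())
  sort(vapply(keep, function(p)
    paste(paste(p$nodes, collapse = "->"),
          paste(p$etypes, collapse = ";"), sep = " | "), ""))
}

# random typed graph (independent of the package's simulator) for
# oracle-equivalence tests
random_typed_graph <- function(n_nodes, edge_prob, seed) {
  set.seed(seed)
  n_gene <- max(1L, rbinom(1, n_nodes, 0.25))
  n_prot <- n_nodes - n_gene
  ids <- c(sprintf("P%d", seq_len(n_prot)), sprintf("G%d", seq_len(n_gene)))
  types <- rep(c("protein", "gene"), c(n_prot, n_gene))
  ntype <- stats::setNames(types, ids)
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  edges <- NULL
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$source[i]; t <- pairs$target[i]
    allowed <- character()
    if (ntype[s] == "protein" && ntype[t] == "protein")
      allowed <- metaboreg:::PROTEIN_LEVEL_TYPES
    if (ntype[s] == "protein" && ntype[t] == "gene")
      allowed <- "expression_regulation"
    if (ntype[s] == "gene" && ntype[t] == "protein")
      allowed <- "encodes"
    for (ty in allowed)
      if (runif(1) < edge_prob)
        edges <- rbind(edges, data.frame(source = s, target = t, type = ty,
                                         sign = "unknown",
                                         stringsAsFactors = FALSE))
  }
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        type = character(), sign = character())
  knowledge_graph(data.frame(id = ids, type = types, stringsAsFactors = FALSE),
                  edges)
}

path_keys <- function(paths)
  sort(paste(paths$nodes, gsub(";", ";", paths$edge_types), sep = " | "))
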