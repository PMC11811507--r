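#' Declarative regulatory-pathway template
#'
#' A template is an ordered list of segments; each segment constrains one or
#' more consecutive path steps: the set of allowed edge types, the node type
#' the step must land on, and a repeat range (`min`..`max`). A path matches
#' the template when some assignment of repeat counts makes its edge-type and
#' node-type sequence conform segment by segment. Paths always start on a
#' protein node (the marker protein) and end on a protein node (the enzyme).
#'
#' @param id template identifier.
#' @param segments list of lists with fields `edge_types` (character),
#'   `node_type` (`"protein"` or `"gene"`), `min`, `max` (non-negative
#'   integers, `max >= min`).
#' @return object of class `path_template`.
#' @export
path_template <- function(id, segments) {
  if (!length(segments)) stop("template needs >= 1 segment", call. = FALSE)
  segments <- lapply(segments, function(s) {
    stopifnot(all(c("edge_types", "node_type") %in% names(s)))
    if (is.null(s$min)) s$min <- 1L
    if (is.null(s$max)) s$max <- s$min
    s$min <- as.integer(s$min); s$max <- as.integer(s$max)
    if (s$max < s$min || s$min < 0L)
      stop("segment repeat range invalid (min=", s$min, ", max=", s$max, ")",
           call. = FALSE)
    bad <- setdiff(s$edge_types, EDGE_TYPES)
    if (length(bad))
      stop("unknown edge type in template: ", bad[1], call. = FALSE)
    if (!s$node_type %in% NODE_TYPES)
      stop("unknown node type in template: ", s$node_type, call. = FALSE)
    s
  })
  last <- segments[[length(segments)]]
  if (last$node_type != "protein")
    stop("template must terminate on a protein (the enzyme)", call. = FALSE)
  structure(list(id = id, segments = segments), class = "path_template")
}

#' @export
print.path_template <- function(x, ...) {
  cat("Template", x$id, "\n")
  for (s in x$segments)
    cat(sprintf("  -[%s]x(%d..%d)-> %s\n",
                paste(s$edge_types, collapse = "|"), s$min, s$max, s$node_type))
  invisible(x)
}

seg <- function(edge_types, node_type, min = 1L, max = min)
  list(edge_types = edge_types, node_type = node_type, min = min, max = max)

#' The four default regulatory-pathway templates
#'
#' Pathways run from a marker protein to a metabolite-converting enzyme:
#' \describe{
#'   \item{T1}{direct protein-level regulation: marker -> enzyme via one
#'     `ppi` or protein-regulation edge.}
#'   \item{T2}{expression regulation: marker -> enzyme gene
#'     (`expression_regulation`) -> enzyme (`encodes`).}
#'   \item{T3}{mediated protein-level regulation: marker -> 1..K intermediate
#'     proteins -> enzyme, all steps protein-level edges.}
#'   \item{T4}{mediated expression regulation: marker -> 1..K intermediate
#'     proteins -> enzyme gene -> enzyme.}
#' }
#' T3/T4 require at least one intermediate, so no path matches two default
#' templates. Protein-level edges are `ppi` and the five protein-regulation
#' kinds (activity, degradation, transport, proteolysis, catalysis).
#'
#' @param max_intermediates K, the largest number of intermediate proteins in
#'   T3/T4 (default 1; enumeration cost grows combinatorially with K).
#' @return list of 4 [path_template] objects named T1..T4.
#' @export
default_templates <- function(max_intermediates = 1L) {
  if (max_intermediates < 1L)
    stop("max_intermediates must be >= 1", call. = FALSE)
  K <- as.integer(max_intermediates)
  pl <- PROTEIN_LEVEL_TYPES
  list(
    T1 = path_template("T1", list(seg(pl, "protein"))),
    T2 = path_template("T2", list(seg("expression_regulation", "gene"),
                                  seg("encodes", "protein"))),
    T3 = path_template("T3", list(seg(pl, "protein", min = 1L, max = K),
                                  seg(pl, "protein"))),
    T4 = path_template("T4", list(seg(pl, "protein", min = 1L, max = K),
                                  seg("expression_regulation", "gene"),
                                  seg("encodes", "protein")))
  )
}

#' Read templates from a YAML specification
#'
#' The YAML holds a list of templates, each with `id` and `segments`
#' (each segment: `edge_types`, `node_type`, optional `min`/`max`), so the
#' default pathway types can be replaced without code changes.
#'
#' @param path YAML file path.
#' @return named list of [path_template] objects.
#' @export
read_templates <- function(path) {
  spec <- yaml::read_yaml(path)
  out <- lapply(spec, function(t) path_template(t$id, t$segments))
  stats::setNames(out, vapply(out, `[[`, "", "id"))
}

#' Write templates to YAML
#'
#' @param templates list of [path_template] objects.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_templates <- function(templates, path) {
  spec <- lapply(templates, function(t)
    list(id = t$id, segments = lapply(t$segments, function(s)
      list(edge_types = s$edge_types, node_type = s$node_type,
           min = s$min, max = s$max))))
  yaml::write_yaml(unname(spec), path)
  invisible(path)
}

# expand a template's segments into all concrete step sequences
# (one step = list(edge_types, node_type)) over the repeat ranges
template_step_sequences <- function(template) {
  choices <- lapply(template$segments, function(s) seq.int(s$min, s$max))
  grids <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  seqs <- list()
  for (r in seq_len(nrow(grids))) {
    steps <- list()
    for (j in seq_along(template$segments)) {
      s <- template$segments[[j]]
      reps <- grids[r, j]
      if (reps > 0L)
        steps <- c(steps, rep(list(list(edge_types = s$edge_types,
                                        node_type = s$node_type)), reps))
    }
    if (length(steps)) seqs[[length(seqs) + 1L]] <- steps
  }
  # dedupe sequences (ranges with min=0 can collide)
  keys <- vapply(seqs, function(st)
    paste(vapply(st, function(x)
      paste(paste(sort(x$edge_types), collapse = "|"), x$node_type), ""),
      collapse = ";"), "")
  seqs[!duplicated(keys)]
}
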