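#' Partition two disease marker lists into specific and shared sets
#'
#' Gene symbols are normalized (whitespace-trimmed, upper-cased) and treated
#' as sets; duplicates within a list collapse with a warning. The three
#' output sets are pairwise disjoint and `A_only + shared` recovers list A
#' as a set (likewise B).
#'
#' @param listA,listB non-empty character vectors of gene symbols.
#' @param labels length-2 labels naming the two diseases (used by
#'   [count_paths()] for marker-group annotation).
#' @return object of class `marker_partition`: list with sorted character
#'   vectors `A_only`, `B_only`, `shared` and the `labels`.
#' @export
partition_markers <- function(listA, listB, labels = c("A", "B")) {
  norm <- function(v, nm) {
    v <- toupper(trimws(as.character(v)))
    v <- v[nzchar(v)]
    if (!length(v)) stop("marker list ", nm, " is empty", call. = FALSE)
    if (anyDuplicated(v)) {
      warning("duplicate symbols in list ", nm, " collapsed: ",
              paste(unique(v[duplicated(v)]), collapse = ", "), call. = FALSE)
      v <- unique(v)
    }
    v
  }
  a <- norm(listA, labels[1]); b <- norm(listB, labels[2])
  structure(
    list(A_only = sort(setdiff(a, b)),
         B_only = sort(setdiff(b, a)),
         shared = sort(intersect(a, b)),
         labels = as.character(labels)),
    class = "marker_partition"
  )
}

#' @export
print.marker_partition <- function(x, ...) {
  cat(sprintf("Marker partition: %s-only %d, %s-only %d, shared %d\n",
              x$labels[1], length(x$A_only),
              x$labels[2], length(x$B_only), length(x$shared)))
  invisible(x)
}

#' Read a one-symbol-per-line marker list
#'
#' Blank lines and `#` comments are skipped.
#'
#' @param path file path.
#' @return character vector of symbols (not yet normalized).
#' @export
read_marker_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Write a marker list
#'
#' @param markers character vector of symbols.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_list <- function(markers, path) {
  writeLines(as.character(markers), path)
  invisible(path)
}

#' Read a metabolite-to-enzyme mapping table
#'
#' Five-column TSV with header `metabolite_id`, `enzyme_protein_id`,
#' `enzyme_gene_id`, `role` (`biosynthesis`/`degradation`) and
#' `enzyme_class` (`amino_acid_metabolism`/`acylcarnitine_metabolism`).
#' Validated: non-empty ids, allowed vocabularies, unique
#' (metabolite, enzyme, role) triples, and — when `panel` is given — every
#' metabolite must belong to the panel vocabulary.
#'
#' @param path TSV path; the default is the fixture shipped with the package
#'   (a synthetic stand-in covering the enzymes of the parkinsonism case
#'   study, see `inst/extdata/enzyme_map.tsv`).
#' @param panel optional character vector of valid metabolite ids.
#' @return data.frame of class `enzyme_map`.
#' @export
read_enzyme_map <- function(path = system.file("extdata", "enzyme_map.tsv",
                                               package = "metaboreg"),
                            panel = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("metabolite_id", "enzyme_protein_id", "enzyme_gene_id",
                "role", "enzyme_class")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("enzyme map lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(df$enzyme_protein_id)) || any(!nzchar(df$enzyme_gene_id)))
    stop("empty enzyme id in enzyme map", call. = FALSE)
  bad <- !df$role %in% c("biosynthesis", "degradation")
  if (any(bad))
    stop("unknown role '", df$role[bad][1],
         "'; allowed: biosynthesis, degradation", call. = FALSE)
  bad <- !df$enzyme_class %in% c("amino_acid_metabolism",
                                 "acylcarnitine_metabolism")
  if (any(bad))
    stop("unknown enzyme class '", df$enzyme_class[bad][1], "'", call. = FALSE)
  key <- paste(df$metabolite_id, df$enzyme_protein_id, df$role)
  if (anyDuplicated(key))
    stop("duplicate (metabolite, enzyme, role) record: ",
         key[duplicated(key)][1], call. = FALSE)
  if (!is.null(panel)) {
    unknown <- setdiff(df$metabolite_id, panel)
    if (length(unknown))
      stop("enzyme map metabolites outside the panel: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  class(df) <- c("enzyme_map", "data.frame")
  df
}

#' Enzymes converting a set of significant metabolites
#'
#' Deduplicated union of enzyme records over the given metabolites, keeping
#' gene ids and metabolism-class annotations. Metabolites with no record in
#' the map are reported in the `unmapped` attribute (and a warning), never
#' dropped silently.
#'
#' @param significant character vector of metabolite ids.
#' @param map an `enzyme_map` data.frame.
#' @return data.frame with one row per distinct enzyme protein:
#'   `enzyme_protein_id`, `enzyme_gene_id`, `enzyme_class`, `metabolites`
#'   (ids joined by `;`); attribute `unmapped` lists metabolites without a
#'   mapping.
#' @export
enzymes_for_metabolites <- function(significant, map) {
  stopifnot(inherits(map, "enzyme_map"))
  significant <- unique(as.character(significant))
  hit <- map[map$metabolite_id %in% significant, , drop = FALSE]
  unmapped <- setdiff(significant, hit$metabolite_id)
  if (length(unmapped))
    warning("no enzyme mapping for metabolites: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  if (!nrow(hit)) {
    out <- data.frame(enzyme_protein_id = character(),
                      enzyme_gene_id = character(),
                      enzyme_class = character(),
                      metabolites = character(), stringsAsFactors = FALSE)
  } else {
    sp <- split(hit, hit$enzyme_protein_id)
    out <- do.call(rbind, lapply(sp, function(g) data.frame(
      enzyme_protein_id = g$enzyme_protein_id[1],
      enzyme_gene_id = g$enzyme_gene_id[1],
      enzyme_class = g$enzyme_class[1],
      metabolites = paste(sort(unique(g$metabolite_id)), collapse = ";"),
      stringsAsFactors = FALSE)))
    out <- out[order(out$enzyme_protein_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "unmapped") <- unmapped
  out
}
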