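#' Per-marker pathway counts split by enzyme class
#'
#' The content behind the per-marker histograms: for every marker, the number
#' of enumerated pathways reaching amino-acid-metabolism versus
#' acylcarnitine-metabolism enzymes, sorted by decreasing total.
#'
#' @param counts a `pathway_counts` object from [count_paths()].
#' @return data.frame with columns `marker`, `marker_group`, one count column
#'   per enzyme class present, and `total`.
#' @export
marker_histogram <- function(counts) {
  stopifnot(inherits(counts, "pathway_counts"))
  classes <- sort(unique(counts$enzyme_class))
  out <- data.frame(marker = rownames(counts$counts),
                    marker_group = unname(counts$marker_group),
                    stringsAsFactors = FALSE)
  for (cl in classes) {
    cols <- counts$enzyme_class == cl
    out[[cl]] <- as.integer(rowSums(counts$counts[, cols, drop = FALSE]))
  }
  if (!nrow(out)) { out$total <- integer(); return(out) }
  out$total <- as.integer(rowSums(counts$counts))
  out <- out[order(-out$total, out$marker), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-enzyme pathway counts split by marker group
#'
#' The analog of the per-enzyme regulatory-connection tables: for every
#' enzyme, how many pathways originate from each marker group
#' (disease-A-specific, disease-B-specific, shared).
#'
#' @param counts a `pathway_counts` object.
#' @return data.frame with columns `enzyme`, `enzyme_class`, one count column
#'   per marker group present, and `total`.
#' @export
enzyme_group_counts <- function(counts) {
  stopifnot(inherits(counts, "pathway_counts"))
  groups <- sort(unique(counts$marker_group))
  out <- data.frame(enzyme = colnames(counts$counts),
                    enzyme_class = unname(counts$enzyme_class),
                    stringsAsFactors = FALSE)
  for (g in groups) {
    rows <- counts$marker_group == g
    out[[g]] <- as.integer(colSums(counts$counts[rows, , drop = FALSE]))
  }
  if (!nrow(out)) { out$total <- integer(); return(out) }
  out$total <- as.integer(colSums(counts$counts))
  out <- out[order(-out$total, out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call enzyme specificity from marker-group pathway counts
#'
#' Operationalizes "enzyme specific to a disease": an enzyme is called for
#' the marker group contributing the most pathways to it, provided the top
#' count reaches `min_count` and exceeds the runner-up by the factor
#' `min_margin`; otherwise (including exact ties) the call is `"mixed"`.
#' The margin ratio is top count / max(1, second count). Calls are invariant
#' to marker and enzyme input order.
#'
#' @param counts a `pathway_counts` object.
#' @param min_margin minimum top/second ratio (default 1.5).
#' @param min_count minimum top count (default 1).
#' @return data.frame with one row per enzyme: `enzyme`, `enzyme_class`,
#'   per-group counts, `dominant_group`, `margin_ratio`, `call`.
#' @export
classify_enzyme_specificity <- function(counts, min_margin = 1.5,
                                        min_count = 1L) {
  stopifnot(inherits(counts, "pathway_counts"))
  groups <- sort(unique(counts$marker_group))
  tab <- enzyme_group_counts(counts)
  tab <- tab[order(tab$enzyme), , drop = FALSE]
  gc <- as.matrix(tab[, groups, drop = FALSE])
  call <- character(nrow(tab)); dominant <- character(nrow(tab))
  ratio <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    v <- sort(stats::setNames(as.numeric(gc[i, ]), colnames(gc)),
              decreasing = TRUE)
    top <- v[1]; second <- if (length(v) > 1L) v[2] else 0L
    dominant[i] <- names(v)[1]
    ratio[i] <- top / max(1, second)
    tie <- length(v) > 1L && v[1] == v[2]
    call[i] <- if (!tie && top >= min_count && ratio[i] >= min_margin)
      dominant[i] else "mixed"
  }
  out <- data.frame(enzyme = tab$enzyme, enzyme_class = tab$enzyme_class,
                    stringsAsFactors = FALSE)
  out[groups] <- tab[groups]
  out$dominant_group <- dominant
  out$margin_ratio <- ratio
  out$call <- call
  rownames(out) <- NULL
  out
}

#' Write the summary report bundle of one pipeline run
#'
#' Canonical outputs are machine-readable tables; every figure the package
#' can draw is backed by one of them. Files written under `outdir`:
#' `screening_results.tsv`, `classification.tsv`, `marker_partition.json`,
#' `paths.tsv`, `marker_histograms.tsv`, `enzyme_group_counts.tsv`,
#' `specificity_calls.tsv` and `manifest.json` (effective settings, seed,
#' package version). Re-running with identical inputs is byte-identical.
#'
#' @param screening a `screening_result`.
#' @param partition a `marker_partition`.
#' @param counts a `pathway_counts` object.
#' @param calls output of [classify_enzyme_specificity()].
#' @param outdir output directory (created if needed).
#' @param settings named list of run settings recorded in the manifest.
#' @return invisible character vector of written file paths.
#' @export
render_report <- function(screening, partition, counts, calls, outdir,
                          settings = list()) {
  missing <- c(
    if (!inherits(screening, "screening_result")) "screening",
    if (!inherits(partition, "marker_partition")) "partition",
    if (!inherits(counts, "pathway_counts")) "counts",
    if (!is.data.frame(calls)) "calls"
  )
  if (length(missing))
    stop("missing or invalid report inputs: ",
         paste(missing, collapse = ", "), call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- c(
    wtsv(screening$table, "screening_results.tsv"),
    wtsv(screening$classification, "classification.tsv"),
    wtsv(counts$paths, "paths.tsv"),
    wtsv(marker_histogram(counts), "marker_histograms.tsv"),
    wtsv(enzyme_group_counts(counts), "enzyme_group_counts.tsv"),
    wtsv(calls, "specificity_calls.tsv")
  )
  pj <- file.path(outdir, "marker_partition.json")
  jsonlite::write_json(
    list(A_only = partition$A_only, B_only = partition$B_only,
         shared = partition$shared, labels = partition$labels),
    pj, pretty = TRUE)
  mj <- file.path(outdir, "manifest.json")
  manifest <- list(
    package = "metaboreg",
    version = as.character(utils::packageVersion("metaboreg")),
    alpha = screening$alpha, rule = screening$rule,
    contrasts = screening$contrasts,
    dedupe = counts$dedupe,
    n_paths = sum(counts$counts),
    settings = settings
  )
  jsonlite::write_json(manifest, mj, pretty = TRUE, auto_unbox = TRUE)
  invisible(c(files, pj, mj))
}

#' Bar chart of pathway counts per marker or per enzyme
#'
#' Optional ggplot2 figure mirroring the report tables (headless-safe; the
#' tables remain the canonical output).
#'
#' @param counts a `pathway_counts` object.
#' @param by `"marker"` (bars per marker, filled by enzyme class) or
#'   `"enzyme"` (bars per enzyme, filled by marker group).
#' @return a ggplot object.
#' @export
plot_path_counts <- function(counts, by = c("marker", "enzyme")) {
  by <- match.arg(by)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires ggplot2", call. = FALSE)
  if (by == "marker") {
    tab <- marker_histogram(counts)
    classes <- setdiff(names(tab), c("marker", "marker_group", "total"))
    long <- do.call(rbind, lapply(classes, function(cl)
      data.frame(unit = tab$marker, fill = cl, count = tab[[cl]],
                 stringsAsFactors = FALSE)))
    xlab <- "genetic marker"; flab <- "enzyme class"
  } else {
    tab <- enzyme_group_counts(counts)
    groups <- setdiff(names(tab), c("enzyme", "enzyme_class", "total"))
    long <- do.call(rbind, lapply(groups, function(g)
      data.frame(unit = tab$enzyme, fill = g, count = tab[[g]],
                 stringsAsFactors = FALSE)))
    xlab <- "enzyme"; flab <- "marker group"
  }
  long$unit <- factor(long$unit, levels = tab[[1]])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$unit, y = .data$count,
                                     fill = .data$fill)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = xlab, y = "regulatory pathways", fill = flab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
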