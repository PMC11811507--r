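#' Metabolite profile set
#'
#' Container for a samples x metabolites concentration matrix (micromolar)
#' with per-sample group labels and per-metabolite class annotations. This is
#' the canonical input to [screen_panel()].
#'
#' @param concentrations numeric matrix, samples in rows, metabolites in
#'   columns; dimnames give sample and metabolite ids. Missing measurements
#'   are `NA` (never coded as zero); all observed values must be >= 0.
#' @param groups character or factor of length `nrow(concentrations)`; one
#'   group label per sample. Exactly one level must be the control group.
#' @param metabolite_class named character vector mapping every metabolite id
#'   to `"amino_acid"` or `"acylcarnitine"`; if `NULL`, classes are inferred
#'   from the id naming convention via [infer_metabolite_classes()].
#' @param control_label which group label denotes the control group
#'   (default `"control"`).
#'
#' @return An object of class `metabolite_profiles`.
#' @export
metabolite_profiles <- function(concentrations, groups,
                                metabolite_class = NULL,
                                control_label = "control") {
  if (!is.matrix(concentrations) || !is.numeric(concentrations))
    stop("`concentrations` must be a numeric matrix", call. = FALSE)
  sample_ids <- rownames(concentrations)
  metabolite_ids <- colnames(concentrations)
  if (is.null(sample_ids) || is.null(metabolite_ids))
    stop("`concentrations` must have sample and metabolite dimnames", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "),
         call. = FALSE)
  if (any(concentrations < 0, na.rm = TRUE))
    stop("concentrations must be non-negative", call. = FALSE)
  groups <- as.character(groups)
  if (length(groups) != nrow(concentrations))
    stop("`groups` must have one label per sample", call. = FALSE)
  if (anyNA(groups) || any(!nzchar(groups)))
    stop("every sample must have a group label", call. = FALSE)
  if (!control_label %in% groups)
    stop("control group '", control_label, "' absent from group labels", call. = FALSE)
  if (is.null(metabolite_class))
    metabolite_class <- infer_metabolite_classes(metabolite_ids)
  missing_class <- setdiff(metabolite_ids, names(metabolite_class))
  if (length(missing_class))
    stop("no class for metabolites: ", paste(missing_class, collapse = ", "),
         call. = FALSE)
  metabolite_class <- metabolite_class[metabolite_ids]
  bad <- !metabolite_class %in% METABOLITE_CLASSES
  if (any(bad))
    stop("unknown metabolite class '", metabolite_class[bad][1],
         "'; allowed: ", paste(METABOLITE_CLASSES, collapse = ", "), call. = FALSE)
  structure(
    list(
      concentrations = concentrations,
      groups = groups,
      metabolite_class = metabolite_class,
      control_label = control_label
    ),
    class = "metabolite_profiles"
  )
}

#' @export
print.metabolite_profiles <- function(x, ...) {
  cat("Metabolite profile set:", nrow(x$concentrations), "samples x",
      ncol(x$concentrations), "metabolites\n")
  tab <- table(x$groups)
  cat("Groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "[control:", paste0(x$control_label, "]"), "\n")
  ctab <- table(x$metabolite_class)
  cat("Classes:", paste(sprintf("%s (%d)", names(ctab), ctab), collapse = ", "), "\n")
  invisible(x)
}

#' Read a metabolite concentration table
#'
#' Reads a wide-layout table (rows = samples, columns = `sample_id`, a group
#' column, then one column per metabolite) from CSV, TSV or XLSX (first
#' sheet; requires the readxl package). A transposed layout (metabolites in
#' rows) is auto-detected when the group column is absent from the header but
#' present in the first column, and silently pivoted. Empty cells are kept as
#' missing (`NA`), never as zero.
#'
#' @param path file path.
#' @param format `"csv"`, `"tsv"` or `"xlsx"`; default guessed from the file
#'   extension.
#' @param group_column name of the column holding group labels.
#' @param class_map optional named character vector (metabolite id -> class)
#'   or path to a two-column TSV sidecar `metabolite_id<TAB>class`; if `NULL`,
#'   classes are inferred from metabolite naming.
#' @param group_aliases optional named character vector translating the file's
#'   group labels to the labels used downstream, e.g.
#'   `c("Parkinson" = "PD", "Healthy" = "control")`.
#' @param control_label label of the control group after alias translation.
#' @return A [metabolite_profiles] object.
#' @export
read_profiles <- function(path, format = c("auto", "csv", "tsv", "xlsx"),
                          group_column = "group", class_map = NULL,
                          group_aliases = NULL, control_label = "control") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     xlsx = "xlsx",
                     stop("cannot guess format from extension '", ext, "'",
                          call. = FALSE))
  }
  df <- switch(format,
    csv = utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    tsv = utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the readxl package", call. = FALSE)
      as.data.frame(readxl::read_excel(path, sheet = 1),
                    check.names = FALSE, stringsAsFactors = FALSE)
    }
  )
  if (anyDuplicated(names(df)))
    stop("duplicate column in ", basename(path), ": ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "),
         call. = FALSE)
  # transposed layout: metabolites in rows, samples in columns
  if (!group_column %in% names(df) && group_column %in% df[[1]]) {
    ids <- df[[1]]
    mat <- t(as.matrix(df[, -1, drop = FALSE]))
    df <- data.frame(sample_id = rownames(mat), mat,
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[-1] <- ids
    rownames(df) <- NULL
  }
  if (!group_column %in% names(df))
    stop("group column '", group_column, "' not found in ", basename(path),
         call. = FALSE)
  id_col <- if ("sample_id" %in% names(df)) "sample_id" else names(df)[1]
  meta_cols <- setdiff(names(df), c(id_col, group_column))
  conc <- df[meta_cols]
  for (j in seq_along(conc)) {
    v <- conc[[j]]
    if (!is.numeric(v)) {
      v_chr <- trimws(as.character(v))
      v_chr[v_chr %in% c("", "NA")] <- NA
      suppressWarnings(v_num <- as.numeric(v_chr))
      bad <- which(!is.na(v_chr) & is.na(v_num))
      if (length(bad))
        stop("non-numeric concentration at row ", bad[1], ", column '",
             meta_cols[j], "': '", v_chr[bad[1]], "'", call. = FALSE)
      v <- v_num
    }
    conc[[j]] <- v
  }
  mat <- as.matrix(conc)
  rownames(mat) <- as.character(df[[id_col]])
  groups <- as.character(df[[group_column]])
  if (!is.null(group_aliases)) {
    hit <- groups %in% names(group_aliases)
    groups[hit] <- group_aliases[groups[hit]]
  }
  if (is.character(class_map) && length(class_map) == 1L && file.exists(class_map))
    class_map <- read_class_map(class_map)
  metabolite_profiles(mat, groups, metabolite_class = class_map,
                      control_label = control_label)
}

#' Read a metabolite class sidecar file
#'
#' @param path two-column TSV `metabolite_id<TAB>class`, no header required
#'   (a `metabolite_id` header line is tolerated); `#` comment lines allowed.
#' @return named character vector of classes.
#' @export
read_class_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("class map line ", bad[1], " has no tab separator", call. = FALSE)
  ids <- vapply(parts, `[[`, "", 1L)
  cls <- vapply(parts, `[[`, "", 2L)
  keep <- ids != "metabolite_id"
  stats::setNames(cls[keep], ids[keep])
}

#' Write a metabolite profile set
#'
#' Writes the wide CSV/TSV layout read by [read_profiles()]: `sample_id`,
#' `group`, then one column per metabolite. Values are written with full
#' double precision so a write/read round trip reproduces the matrix.
#'
#' @param profiles a [metabolite_profiles] object.
#' @param path output file path.
#' @param format `"csv"` or `"tsv"` (xlsx output is not supported).
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(profiles, "metabolite_profiles"))
  mat <- profiles$concentrations
  df <- data.frame(sample_id = rownames(mat), group = profiles$groups,
                   check.names = FALSE, stringsAsFactors = FALSE)
  conc <- as.data.frame(mat, check.names = FALSE)
  # full precision, locale-independent
  conc[] <- lapply(conc, function(v) {
    out <- vapply(v, function(x) if (is.na(x)) "" else sprintf("%.17g", x), "")
    out
  })
  df <- cbind(df, conc)
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Summarize panel composition
#'
#' @param profiles a [metabolite_profiles] object.
#' @return list with `n_samples`, `n_metabolites`, `n_per_class` (named
#'   integer), `n_per_group` (named integer) and `n_missing` (count of `NA`
#'   concentration cells).
#' @export
summarize_panel <- function(profiles) {
  stopifnot(inherits(profiles, "metabolite_profiles"))
  cls <- factor(profiles$metabolite_class, levels = METABOLITE_CLASSES)
  list(
    n_samples = nrow(profiles$concentrations),
    n_metabolites = ncol(profiles$concentrations),
    n_per_class = table(cls),
    n_per_group = table(profiles$groups),
    n_missing = sum(is.na(profiles$concentrations))
  )
}
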