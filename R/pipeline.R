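#' Pipeline run configuration
#'
#' Collects file paths and settings for an end-to-end run; all fields can
#' also be supplied via a YAML file ([read_run_config()]). Referenced files
#' are checked at construction.
#'
#' @param profiles path to a concentration table readable by
#'   [read_profiles()].
#' @param markers_a,markers_b paths to one-symbol-per-line marker lists.
#' @param enzyme_map path to the metabolite-to-enzyme TSV; default the
#'   shipped fixture.
#' @param graph path to a typed interaction graph readable by
#'   [read_graph_file()].
#' @param templates optional YAML template spec ([read_templates()]);
#'   `NULL` uses [default_templates()].
#' @param disease_labels length-2 labels for the two disease groups, in the
#'   order the group column uses.
#' @param control_label control group label in the profile table.
#' @param alpha FDR threshold.
#' @param rule test combination rule, see [screen_panel()].
#' @param max_intermediates K for the mediated templates.
#' @param dedupe `"paths"` or `"pairs"`, see [count_paths()].
#' @param min_margin,min_count specificity-call thresholds, see
#'   [classify_enzyme_specificity()].
#' @param outdir output directory for [render_report()].
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters only when inputs are simulated).
#' @return list of class `run_config`.
#' @export
run_config <- function(profiles, markers_a, markers_b,
                       enzyme_map = system.file("extdata", "enzyme_map.tsv",
                                               package = "metaboreg"),
                       graph, templates = NULL,
                       disease_labels = c("PD", "VP"),
                       control_label = "control",
                       alpha = 0.05, rule = "both",
                       max_intermediates = 1L, dedupe = "paths",
                       min_margin = 1.5, min_count = 1L,
                       outdir = "metaboreg_run", seed = 1L) {
  paths <- c(profiles = profiles, markers_a = markers_a,
             markers_b = markers_b, enzyme_map = enzyme_map, graph = graph)
  if (!is.null(templates)) paths <- c(paths, templates = templates)
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop("input file(s) not found: ",
         paste(sprintf("%s (%s)", absent, names(absent)), collapse = ", "),
         call. = FALSE)
  structure(
    list(profiles = profiles, markers_a = markers_a, markers_b = markers_b,
         enzyme_map = enzyme_map, graph = graph, templates = templates,
         disease_labels = disease_labels, control_label = control_label,
         alpha = alpha, rule = rule,
         max_intermediates = as.integer(max_intermediates), dedupe = dedupe,
         min_margin = min_margin, min_count = as.integer(min_count),
         outdir = outdir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of [run_config()];
#'   relative file paths are resolved against the YAML's directory.
#' @param ... overrides applied on top of the file's values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  base <- dirname(normalizePath(path))
  for (f in c("profiles", "markers_a", "markers_b", "enzyme_map", "graph",
              "templates")) {
    if (!is.null(vals[[f]]) && !file.exists(vals[[f]]))
      vals[[f]] <- file.path(base, vals[[f]])
  }
  do.call(run_config, vals)
}

#' Run the full screening-to-report pipeline
#'
#' Stages: read profiles -> screen -> partition markers -> map significant
#' metabolites to enzymes -> enumerate template paths marker-to-enzyme ->
#' aggregate counts -> write report bundle. Each stage consumes only files
#' or the previous stage's return value; a failure stops with the stage
#' name. Deterministic: identical config and inputs give byte-identical
#' outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return invisible list with every stage's object (`profiles`,
#'   `screening`, `partition`, `enzymes`, `graph`, `paths`, `counts`,
#'   `calls`, `files`).
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say(sprintf("[%s] done in %.2fs", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  profiles <- stage("read_profiles",
    read_profiles(config$profiles, control_label = config$control_label))
  screening <- stage("screen",
    screen_panel(profiles, alpha = config$alpha, rule = config$rule))
  partition <- stage("partition",
    partition_markers(read_marker_list(config$markers_a),
                      read_marker_list(config$markers_b),
                      labels = config$disease_labels))
  emap <- stage("enzyme_map",
    read_enzyme_map(config$enzyme_map,
                    panel = colnames(profiles$concentrations)))
  sig <- significant_metabolites(screening)
  union_sig <- sort(unique(unlist(sig[screening$diseases])))
  enzymes <- stage("map_enzymes",
    suppressWarnings(enzymes_for_metabolites(union_sig, emap)))
  graph <- stage("read_graph", read_graph_file(config$graph))
  templates <- stage("templates",
    if (is.null(config$templates))
      default_templates(config$max_intermediates)
    else read_templates(config$templates))
  all_markers <- sort(unique(c(partition$A_only, partition$B_only,
                               partition$shared)))
  paths <- stage("find_paths",
    suppressWarnings(enumerate_all_templates(
      graph, sources = all_markers,
      targets = enzymes$enzyme_protein_id, templates = templates)))
  counts <- stage("count_paths",
    suppressWarnings(count_paths(paths, partition, emap,
                                 dedupe = config$dedupe)))
  calls <- stage("classify",
    classify_enzyme_specificity(counts, min_margin = config$min_margin,
                                min_count = config$min_count))
  files <- stage("report",
    render_report(screening, partition, counts, calls, config$outdir,
                  settings = list(
                    profiles = basename(config$profiles),
                    markers_a = basename(config$markers_a),
                    markers_b = basename(config$markers_b),
                    enzyme_map = basename(config$enzyme_map),
                    graph = basename(config$graph),
                    alpha = config$alpha, rule = config$rule,
                    max_intermediates = config$max_intermediates,
                    dedupe = config$dedupe,
                    min_margin = config$min_margin,
                    min_count = config$min_count,
                    seed = config$seed)))
  invisible(list(profiles = profiles, screening = screening,
                 partition = partition, enzymes = enzymes, graph = graph,
                 paths = paths, counts = counts, calls = calls,
                 files = files))
}
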