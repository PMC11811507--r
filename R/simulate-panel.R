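#' Configuration for a simulated metabolite panel
#'
#' Describes a three-group case/case/control study of a targeted metabolite
#' panel. Per-metabolite concentrations are log-normal: the log-concentration
#' of metabolite i in sample s is Normal(mu_i + shift_i(g), cv), where
#' shift_i(g) = `log_fold_shift` when metabolite i is in the effect set of
#' sample s's disease group, and 0 otherwise. Baseline log-means mu_i are
#' drawn once per seed, uniform on log(1)..log(100) micromolar.
#'
#' @param group_sizes integer vector of length 3: disease A, disease B,
#'   control sample counts (defaults 9, 9, 17 — a small case/control design
#'   typical of targeted parkinsonism panels).
#' @param group_labels labels for the three groups (third is the control).
#' @param metabolites data.frame with `metabolite_id` and `class` columns;
#'   default the 44-analyte panel of [default_panel_metabolites()].
#' @param effect_metabolites_A,effect_metabolites_B character vectors of
#'   metabolite ids with a planted shift in group A / group B.
#' @param log_fold_shift planted location shift on the natural-log scale.
#' @param cv log-scale standard deviation (> 0).
#' @param seed integer seed; all randomness is local to the call.
#' @return list of class `panel_sim_config`.
#' @export
panel_sim_config <- function(group_sizes = c(9L, 9L, 17L),
                             group_labels = c("diseaseA", "diseaseB", "control"),
                             metabolites = default_panel_metabolites(),
                             effect_metabolites_A = character(),
                             effect_metabolites_B = character(),
                             log_fold_shift = 2.0,
                             cv = 0.3,
                             seed = 1L) {
  if (length(group_sizes) != 3L || any(group_sizes < 2L))
    stop("three group sizes >= 2 required", call. = FALSE)
  if (length(group_labels) != 3L || anyDuplicated(group_labels))
    stop("three distinct group labels required", call. = FALSE)
  if (!all(c("metabolite_id", "class") %in% names(metabolites)))
    stop("`metabolites` needs metabolite_id and class columns", call. = FALSE)
  unknown <- setdiff(c(effect_metabolites_A, effect_metabolites_B),
                     metabolites$metabolite_id)
  if (length(unknown))
    stop("effect metabolites not in panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.numeric(cv) || cv <= 0) stop("cv must be > 0", call. = FALSE)
  structure(
    list(group_sizes = as.integer(group_sizes),
         group_labels = as.character(group_labels),
         metabolites = metabolites,
         effect_metabolites_A = unique(effect_metabolites_A),
         effect_metabolites_B = unique(effect_metabolites_B),
         log_fold_shift = log_fold_shift,
         cv = cv,
         seed = as.integer(seed)),
    class = "panel_sim_config"
  )
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a metabolite concentration panel
#'
#' @param config a [panel_sim_config()].
#' @return A [metabolite_profiles] object; strictly positive concentrations,
#'   bit-identical for identical configs.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  with_local_seed(config$seed, {
    ids <- config$metabolites$metabolite_id
    m <- length(ids)
    n <- sum(config$group_sizes)
    groups <- rep(config$group_labels, config$group_sizes)
    mu <- stats::runif(m, min = log(1), max = log(100))
    shift <- matrix(0, n, m)
    shift[groups == config$group_labels[1], ids %in% config$effect_metabolites_A] <-
      config$log_fold_shift
    shift[groups == config$group_labels[2], ids %in% config$effect_metabolites_B] <-
      config$log_fold_shift
    logc <- matrix(stats::rnorm(n * m, mean = 0, sd = config$cv), n, m)
    logc <- sweep(logc, 2, mu, `+`) + shift
    mat <- exp(logc)
    rownames(mat) <- sprintf("S%03d", seq_len(n))
    colnames(mat) <- ids
    metabolite_profiles(
      mat, groups,
      metabolite_class = stats::setNames(config$metabolites$class, ids),
      control_label = config$group_labels[3]
    )
  })
}

#' Significance pattern of the parkinsonism case study
#'
#' The published screening pattern for the 44-analyte panel: 17 metabolites
#' shared between Parkinson's disease (PD) and vascular parkinsonism (VP) —
#' four amino acids (alanine, proline, isoleucine, valine) and 13
#' acylcarnitines — plus methionine altered only in PD and free carnitine,
#' C6, C10 and C10:1 altered only in VP; 18 significant metabolites in PD
#' and 21 in VP overall.
#'
#' @return list with character vectors `shared`, `pd_only`, `vp_only`,
#'   `pd` (= shared + pd_only) and `vp` (= shared + vp_only).
#' @export
study_significance_pattern <- function() {
  shared_aa <- c("Ala", "Pro", "Ile", "Val")
  shared_ac <- c("C2", "C3", "C4", "C5", "C8", "C12", "C14", "C14:1",
                 "C16", "C16:1", "C18", "C18:1", "C18:2")
  shared <- c(shared_aa, shared_ac)
  pd_only <- "Met"
  vp_only <- c("C0", "C6", "C10", "C10:1")
  list(shared = shared, pd_only = pd_only, vp_only = vp_only,
       pd = c(shared, pd_only), vp = c(shared, vp_only))
}

#' Simulate a panel mirroring the parkinsonism case study design
#'
#' Synthetic stand-in for the study's plasma panel (the original cohort table
#' is not redistributable): group sizes 9 (PD), 9 (VP), 17 (control) over the
#' default 44-metabolite panel, with the published significance pattern
#' (see [study_significance_pattern()]) planted as log-scale location shifts.
#'
#' @param seed integer seed.
#' @param log_fold_shift,cv passed to [panel_sim_config()].
#' @return A [metabolite_profiles] object with groups `PD`, `VP`, `control`.
#' @export
simulate_study_panel <- function(seed = 1L, log_fold_shift = 2.0, cv = 0.3) {
  pat <- study_significance_pattern()
  cfg <- panel_sim_config(
    group_sizes = c(9L, 9L, 17L),
    group_labels = c("PD", "VP", "control"),
    effect_metabolites_A = pat$pd,
    effect_metabolites_B = pat$vp,
    log_fold_shift = log_fold_shift,
    cv = cv,
    seed = seed
  )
  simulate_panel(cfg)
}

#' Simulate two gene-marker lists with a controlled overlap
#'
#' @param nA,nB list sizes; `n_shared` the exact intersection size.
#' @param seed integer seed.
#' @param prefix symbol prefix for generated gene ids.
#' @return list with character vectors `listA` and `listB`;
#'   `length(intersect(listA, listB)) == n_shared` exactly.
#' @export
simulate_marker_lists <- function(nA, nB, n_shared, seed = 1L, prefix = "GM") {
  if (n_shared > min(nA, nB))
    stop("n_shared exceeds the smaller list size", call. = FALSE)
  with_local_seed(seed, {
    total <- nA + nB - n_shared
    pool <- sprintf("%s%04d", prefix, sample.int(9999L, total))
    shared <- pool[seq_len(n_shared)]
    a_only <- pool[seq_len(nA - n_shared) + n_shared]
    b_only <- pool[seq_len(nB - n_shared) + nA]
    list(listA = sample(c(shared, a_only)),
         listB = sample(c(shared, b_only)))
  })
}
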