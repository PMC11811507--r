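#' Two-sample Mann-Whitney U test
#'
#' Wrapper around [stats::wilcox.test()] with an explicit branch policy:
#' the exact null distribution is used when the smaller sample has at most
#' 12 observations and the pooled data are tie-free; otherwise the normal
#' approximation with midrank tie correction and continuity correction is
#' used. The two-sided exact p-value follows the doubling convention
#' (twice the smaller tail, capped at 1), which equals the full
#' permutation-enumeration p-value for tie-free data.
#'
#' @param x,y numeric vectors, each of length >= 2 (NAs dropped).
#' @return list with `U` (statistic for `x`), `p`, `method` (`"exact"` or
#'   `"normal_approx"`), and `degenerate` (TRUE when all pooled values are
#'   identical, in which case `p` is 1).
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs >= 2 non-missing values", call. = FALSE)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1,
                method = "degenerate", degenerate = TRUE))
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- !ties && min(length(x), length(y)) <= 12L
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  list(U = unname(ht$statistic), p = ht$p.value,
       method = if (use_exact) "exact" else "normal_approx",
       degenerate = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Wrapper around [stats::ks.test()]: D is the supremum distance between the
#' two empirical CDFs; the exact conditional p-value is used when both
#' samples have at most 12 observations and the pooled data are tie-free
#' (where it equals the permutation-enumeration p-value), otherwise the
#' asymptotic distribution.
#'
#' @inheritParams mann_whitney
#' @return list with `D`, `p`, `method`, `degenerate`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs >= 2 non-missing values", call. = FALSE)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(D = 0, p = 1, method = "degenerate", degenerate = TRUE))
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- !ties && max(length(x), length(y)) <= 12L
  ht <- suppressWarnings(stats::ks.test(x, y, exact = use_exact))
  list(D = unname(ht$statistic), p = ht$p.value,
       method = if (use_exact) "exact" else "asymptotic",
       degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()] after validating the input
#' range; output order matches input order.
#'
#' @param pvals numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stop("p-values must be numeric", call. = FALSE)
  bad <- which(is.na(pvals) | pvals < 0 | pvals > 1)
  if (length(bad))
    stop("p-value outside [0, 1] at position ", bad[1], call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Differential screening of a metabolite panel
#'
#' For every disease group versus the control group, runs the Mann-Whitney
#' and Kolmogorov-Smirnov tests on each metabolite (missing values removed
#' pairwise per metabolite), applies Benjamini-Hochberg FDR across
#' metabolites separately for each test within each contrast, calls a
#' metabolite significant for a contrast per the combination `rule`, and —
#' when exactly two disease groups are present — classifies each metabolite
#' as specific to one disease, shared, or none.
#'
#' @param profiles a [metabolite_profiles] object with a control group and
#'   one or two disease groups.
#' @param alpha FDR threshold (default 0.05).
#' @param rule how the two tests combine into one significance call per
#'   contrast: `"both"` (both BH-adjusted p < alpha; default), `"either"`,
#'   `"mw_only"`, or `"ks_only"`.
#' @return An object of class `screening_result`: list with `table` (one row
#'   per contrast x metabolite: sample sizes, U, D, raw and adjusted
#'   p-values, significance flag), `classification` (per metabolite:
#'   `<disease>_specific`, `shared` or `none`; only for two-disease designs),
#'   `alpha`, `rule`, `contrasts`.
#' @export
screen_panel <- function(profiles, alpha = 0.05,
                         rule = c("both", "either", "mw_only", "ks_only")) {
  stopifnot(inherits(profiles, "metabolite_profiles"))
  rule <- match.arg(rule)
  groups <- profiles$groups
  control <- profiles$control_label
  diseases <- setdiff(unique(groups), control)
  if (length(diseases) < 1L)
    stop("no disease group to contrast against the control", call. = FALSE)
  mat <- profiles$concentrations
  mets <- colnames(mat)

  rows <- list()
  for (d in diseases) {
    case_idx <- groups == d
    ctrl_idx <- groups == control
    m_len <- length(mets)
    n_case <- n_control <- integer(m_len)
    U <- p_mw <- D <- p_ks <- numeric(m_len)
    mw_method <- ks_method <- character(m_len)
    degenerate <- logical(m_len)
    for (i in seq_len(m_len)) {
      x <- mat[case_idx, i]; y <- mat[ctrl_idx, i]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      mw <- mann_whitney(x, y)
      ks <- ks_two_sample(x, y)
      n_case[i] <- length(x); n_control[i] <- length(y)
      U[i] <- mw$U; p_mw[i] <- mw$p; mw_method[i] <- mw$method
      D[i] <- ks$D; p_ks[i] <- ks$p; ks_method[i] <- ks$method
      degenerate[i] <- mw$degenerate || ks$degenerate
    }
    tab <- data.frame(
      contrast = paste0(d, "_vs_", control),
      disease = d, metabolite = mets,
      class = unname(profiles$metabolite_class[mets]),
      n_case = n_case, n_control = n_control,
      U = U, p_mw = p_mw, mw_method = mw_method,
      D = D, p_ks = p_ks, ks_method = ks_method,
      degenerate = degenerate,
      stringsAsFactors = FALSE
    )
    tab$q_mw <- bh_adjust(tab$p_mw)
    tab$q_ks <- bh_adjust(tab$p_ks)
    tab$significant <- switch(rule,
      both    = tab$q_mw < alpha & tab$q_ks < alpha,
      either  = tab$q_mw < alpha | tab$q_ks < alpha,
      mw_only = tab$q_mw < alpha,
      ks_only = tab$q_ks < alpha
    )
    rows[[d]] <- tab
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  classification <- NULL
  if (length(diseases) == 2L) {
    sigA <- table$metabolite[table$disease == diseases[1] & table$significant]
    sigB <- table$metabolite[table$disease == diseases[2] & table$significant]
    category <- ifelse(
      mets %in% sigA & mets %in% sigB, "shared",
      ifelse(mets %in% sigA, paste0(diseases[1], "_specific"),
             ifelse(mets %in% sigB, paste0(diseases[2], "_specific"), "none"))
    )
    classification <- data.frame(
      metabolite = mets,
      class = unname(profiles$metabolite_class[mets]),
      category = category,
      stringsAsFactors = FALSE
    )
  }

  structure(
    list(table = table, classification = classification,
         alpha = alpha, rule = rule,
         contrasts = paste0(diseases, "_vs_", control),
         diseases = diseases, control = control),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Screening result (rule =", x$rule, ", alpha =", x$alpha, ")\n")
  for (d in x$diseases) {
    n_sig <- sum(x$table$significant[x$table$disease == d])
    cat("  ", d, "vs", x$control, ":", n_sig, "significant metabolites\n")
  }
  if (!is.null(x$classification)) {
    tab <- table(x$classification$category)
    cat("  Classification:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-metabolite significant sets from a screening result
#'
#' @param screening a `screening_result`.
#' @return named list of character vectors: one element per disease contrast
#'   (significant metabolite ids) plus `shared` when two diseases were
#'   screened.
#' @export
significant_metabolites <- function(screening) {
  stopifnot(inherits(screening, "screening_result"))
  out <- lapply(screening$diseases, function(d)
    screening$table$metabolite[screening$table$disease == d &
                               screening$table$significant])
  names(out) <- screening$diseases
  if (length(screening$diseases) == 2L)
    out$shared <- intersect(out[[1]], out[[2]])
  out
}
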