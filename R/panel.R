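#' Default metabolite panel vocabulary
#'
#' The 44-analyte targeted panel used throughout the package: 14 proteinogenic
#' and urea-cycle amino acids (three-letter codes) and 30 acylcarnitines named
#' by acyl chain (C0 = free carnitine, C2 = acetylcarnitine, ..., C18:1 =
#' oleoylcarnitine; OH = hydroxylated, DC = dicarboxylic).
#'
#' @return A data.frame with columns `metabolite_id` and `class`
#'   (`amino_acid` or `acylcarnitine`).
#' @export
default_panel_metabolites <- function() {
  amino_acids <- c(
    "Ala", "Arg", "Asp", "Cit", "Glu", "Gly", "Ile",
    "Leu", "Met", "Orn", "Phe", "Pro", "Tyr", "Val"
  )
  acylcarnitines <- c(
    "C0", "C2", "C3", "C4", "C5", "C5:1", "C5DC", "C5OH",
    "C6", "C6DC", "C8", "C8:1", "C10", "C10:1", "C10:2",
    "C12", "C12:1", "C14", "C14:1", "C14:2", "C14OH",
    "C16", "C16:1", "C16OH", "C16:1OH", "C18", "C18:1",
    "C18:2", "C18OH", "C18:1OH"
  )
  data.frame(
    metabolite_id = c(amino_acids, acylcarnitines),
    class = rep(c("amino_acid", "acylcarnitine"),
                c(length(amino_acids), length(acylcarnitines))),
    stringsAsFactors = FALSE
  )
}

#' Infer metabolite classes from panel naming conventions
#'
#' Ids matching the acylcarnitine chain-name pattern (`C` followed by digits,
#' optionally `:n`, `OH`, `DC`) are classed `acylcarnitine`; everything else
#' (three-letter amino-acid codes) is classed `amino_acid`.
#'
#' @param metabolite_ids character vector of panel analyte names.
#' @return named character vector of classes.
#' @export
infer_metabolite_classes <- function(metabolite_ids) {
  is_ac <- grepl("^C[0-9]+(:[0-9]+)?(OH|DC)?$", metabolite_ids)
  stats::setNames(ifelse(is_ac, "acylcarnitine", "amino_acid"), metabolite_ids)
}

METABOLITE_CLASSES <- c("amino_acid", "acylcarnitine")
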