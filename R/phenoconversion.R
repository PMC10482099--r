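#' Construct a medication record tibble
#'
#' @param drug Character vector of medication names (free text; brand names
#'   are resolved against the bundle's synonym map where needed).
#' @param route Administration route, one of `"oral"`, `"topical"`, `"other"`.
#' @param active Logical; whether the prescription is currently active.
#' @return Tibble with columns `drug`, `route`, `active`.
#' @export
medication_record <- function(drug, route = "oral", active = TRUE) {
  if (any(is.na(drug) | str_trim(drug) == "")) {
    abort("drug name must be non-empty", class = "pgx_input_error")
  }
  bad <- setdiff(unique(route), c("oral", "topical", "other"))
  if (length(bad) > 0) {
    abort(sprintf("unknown route token(s): %s", paste(bad, collapse = ", ")),
          class = "pgx_input_error")
  }
  tibble(drug = tolower(str_trim(drug)),
         route = rep_len(route, length(drug)),
         active = rep_len(active, length(drug)))
}

empty_medications <- function() medication_record(character(0))[0, ]

#' Strongest CYP2D6 inhibitor in a medication list
#'
#' Looks up every active, systemically administered medication (any route
#' other than topical) in the bundle's inhibitor table and returns the
#' maximum inhibition strength found.
#'
#' @param medications Medication tibble (see [medication_record()]).
#' @param bundle Reference bundle.
#' @return `"none"`, `"moderate"` or `"strong"`.
#' @export
#'
#' @examples
#' bundle <- load_reference_bundle()
#' inhibitor_strength(medication_record("paroxetine"), bundle)  # "strong"
inhibitor_strength <- function(medications, bundle) {
  if (is.null(medications) || nrow(medications) == 0) return("none")
  meds <- medications |>
    filter(.data$active, .data$route != "topical") |>
    mutate(drug = normalize_drug(.data$drug, bundle))
  hits <- bundle$inhibitors |>
    filter(.data$gene == "CYP2D6", .data$drug %in% meds$drug)
  if (nrow(hits) == 0) return("none")
  if ("strong" %in% hits$strength) "strong" else "moderate"
}

# Moderate inhibition steps the metabolizer label down one rank under the
# legacy cutoffs (halving the activity score would leave a 2.0-score NM at
# 1.0, still NM, and therefore never convert normal metabolizers).
MODERATE_STEP <- c("UM" = "NM", "RM" = "NM", "NM" = "IM", "IM" = "PM",
                   "PM" = "PM")

#' Convert a CYP2D6 genotype-based phenotype to a clinical phenotype
#'
#' Drug-induced phenoconversion: a strong CYP2D6 inhibitor renders any
#' metabolizer a clinical poor metabolizer; a moderate inhibitor steps the
#' label down one rank; no inhibitor leaves the label unchanged. Genes other
#' than CYP2D6 pass through with strength recorded as `"none"`, and an
#' indeterminate genotype-based phenotype stays indeterminate.
#'
#' @param call One-row phenotype tibble from [assign_phenotype()].
#' @param strength Inhibitor strength: `"none"`, `"moderate"` or `"strong"`.
#' @return The input row extended with `inhibitor_strength_applied`,
#'   `clinical_phenotype` and `phenoconverted`.
#' @export
#'
#' @examples
#' bundle <- load_reference_bundle()
#' d <- tibble::tibble(gene = "CYP2D6", allele_1 = "*1", allele_2 = "*1",
#'                     diplotype = "*1/*1", determinate = TRUE,
#'                     ambiguity_note = "")
#' nm <- assign_phenotype(d, bundle = bundle)
#' phenoconvert(nm, "strong")$clinical_phenotype  # "PM"
phenoconvert <- function(call, strength) {
  if (!strength %in% c("none", "moderate", "strong")) {
    abort(sprintf("unknown inhibitor strength token: %s", strength),
          class = "pgx_input_error")
  }
  base <- call$genotype_based_phenotype
  out <- call
  if (call$gene != "CYP2D6") {
    out$inhibitor_strength_applied <- "none"
    out$clinical_phenotype <- base
    out$phenoconverted <- FALSE
    return(out)
  }
  out$inhibitor_strength_applied <- strength
  if (identical(base, "indeterminate") || strength == "none") {
    out$clinical_phenotype <- base
  } else if (strength == "strong") {
    out$clinical_phenotype <- "PM"
  } else {
    out$clinical_phenotype <- unname(MODERATE_STEP[base])
  }
  out$phenoconverted <- !identical(out$clinical_phenotype, base) &&
    !identical(base, "indeterminate")
  out
}
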