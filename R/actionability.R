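#' Active panel-drug prescriptions in a medication list
#'
#' Matches every active medication against the 27-drug panel rules, honouring
#' each rule's eligible administration routes (topical tacrolimus, for
#' example, is not a systemic exposure and does not match). A drug governed
#' by rules for two genes yields one match per gene.
#'
#' @param medications Medication tibble (see [medication_record()]).
#' @param bundle Reference bundle.
#' @return Tibble of matches: `drug`, `gene`, `route`, plus the matched
#'   rule's `actionable_phenotypes`, `future_watch_phenotypes` and
#'   `evidence_grade`; zero rows when nothing matches.
#' @export
#'
#' @examples
#' bundle <- load_reference_bundle()
#' active_panel_drugs(medication_record("omeprazole"), bundle)$gene  # CYP2C19
active_panel_drugs <- function(medications, bundle) {
  empty <- bundle$panel_rules[0, ] |>
    mutate(route = character(0)) |>
    select("drug", "gene", "route", "actionable_phenotypes",
           "future_watch_phenotypes", "evidence_grade")
  if (is.null(medications) || nrow(medications) == 0) return(empty)
  meds <- medications |>
    filter(.data$active) |>
    mutate(drug = normalize_drug(.data$drug, bundle)) |>
    distinct(.data$drug, .data$route)
  if (nrow(meds) == 0) return(empty)
  joined <- inner_join(meds, bundle$panel_rules, by = "drug",
                       relationship = "many-to-many")
  joined |>
    filter(map2_lgl(.data$route, .data$eligible_routes,
                    ~ .x %in% .y)) |>
    distinct(.data$drug, .data$gene, .keep_all = TRUE) |>
    select("drug", "gene", "route", "actionable_phenotypes",
           "future_watch_phenotypes", "evidence_grade")
}

#' Classify one gene-drug pair for current actionability
#'
#' A pair is currently actionable when the patient's clinical phenotype (the
#' genotype-based phenotype after any CYP2D6 phenoconversion) is in the
#' rule's actionable set, i.e. the guideline recommendation is a drug or dose
#' change. Phenotypes in the rule's future-watch set are flagged as
#' potentially actionable in the future (e.g. proton pump inhibitors in
#' CYP2C19 normal or rapid metabolizers, pending indication-based guidance).
#' An indeterminate phenotype triggers neither.
#'
#' @param match One-row match tibble from [active_panel_drugs()].
#' @param clinical_phenotype Clinical phenotype label for the match's gene.
#' @return One-row tibble: `drug`, `gene`, `clinical_phenotype`,
#'   `currently_actionable`, `future_watch`, `evidence_grade`.
#' @export
classify_gene_drug_pair <- function(match, clinical_phenotype) {
  actionable <- clinical_phenotype %in% match$actionable_phenotypes[[1]]
  future <- clinical_phenotype %in% match$future_watch_phenotypes[[1]]
  if (identical(clinical_phenotype, "indeterminate")) {
    actionable <- FALSE
    future <- FALSE
  }
  tibble(drug = match$drug, gene = match$gene,
         clinical_phenotype = clinical_phenotype,
         currently_actionable = actionable,
         future_watch = future && !actionable,
         evidence_grade = match$evidence_grade)
}

#' Does a genotype profile carry any potentially actionable phenotype?
#'
#' A profile is potentially actionable when any gene's genotype-based
#' phenotype falls in the actionable set of any panel rule for that gene,
#' regardless of what the patient is currently taking. Indeterminate
#' phenotypes never trigger.
#'
#' @param phenotypes Tibble of per-gene phenotype calls with columns `gene`
#'   and `genotype_based_phenotype` (one row per panel gene).
#' @param bundle Reference bundle.
#' @return List with `actionable` (logical) and `genes` (character vector of
#'   triggering genes).
#' @export
potentially_actionable_profile <- function(phenotypes, bundle) {
  actionable_by_gene <- bundle$panel_rules |>
    select("gene", "actionable_phenotypes") |>
    tidyr::unnest_longer("actionable_phenotypes", values_to = "phenotype") |>
    distinct(.data$gene, .data$phenotype)
  hits <- phenotypes |>
    filter(.data$genotype_based_phenotype != "indeterminate") |>
    inner_join(actionable_by_gene,
               by = c(gene = "gene", genotype_based_phenotype = "phenotype"))
  list(actionable = nrow(hits) > 0, genes = unique(hits$gene))
}

#' Screen a patient against the pilot's eligibility criteria
#'
#' Inclusion requires age 18 or older, active benefit-plan enrollment, at
#' least one active panel-drug prescription (any duration of therapy), and an
#' outpatient visit within the preceding 12 months; prior pharmacogenetic
#' testing excludes. Every failed criterion is reported.
#'
#' @param age Age in years.
#' @param plan_enrolled Logical; active benefit-plan enrollment.
#' @param last_visit_days Days since the most recent outpatient visit.
#' @param medications Medication tibble.
#' @param prior_pgx Logical; previous pharmacogenetic testing.
#' @param bundle Reference bundle.
#' @return List with `eligible` (logical) and `reasons` (character vector,
#'   empty iff eligible).
#' @export
#'
#' @examples
#' bundle <- load_reference_bundle()
#' screen_eligibility(45, TRUE, 100, medication_record("omeprazole"),
#'                    FALSE, bundle)$eligible  # TRUE
screen_eligibility <- function(age, plan_enrolled, last_visit_days,
                               medications, prior_pgx, bundle) {
  if (is.na(age) || age < 0) {
    abort("age must be non-negative", class = "pgx_input_error")
  }
  if (is.na(last_visit_days) || last_visit_days < 0) {
    abort("last_visit_days must be non-negative", class = "pgx_input_error")
  }
  reasons <- character(0)
  if (age < 18) reasons <- c(reasons, "under 18")
  if (!isTRUE(plan_enrolled)) reasons <- c(reasons, "not plan-enrolled")
  if (nrow(active_panel_drugs(medications, bundle)) == 0) {
    reasons <- c(reasons, "no active panel drug")
  }
  if (last_visit_days > 365) reasons <- c(reasons, "no visit in 12 months")
  if (isTRUE(prior_pgx)) reasons <- c(reasons, "prior PGx test")
  list(eligible = length(reasons) == 0, reasons = reasons)
}
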