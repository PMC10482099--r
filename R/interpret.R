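#' Interpret one patient end to end
#'
#' Composes the pipeline for a single patient: diplotype inference and
#' phenotype translation for all eight panel genes, CYP2D6 inhibitor lookup
#' and phenoconversion, active panel-drug matching, per-pair actionability
#' classification, and the potential-actionability profile.
#'
#' @param patient A `pgx_patient` record (fields `sample_id`, `snp_calls`,
#'   `medications`; see [fixture_cohort_table3()] or [simulate_cohort()]),
#'   or any list with those fields.
#' @param bundle Reference bundle.
#' @return List: `sample_id`, `inhibitor_strength`, `phenotypes` (per-gene
#'   tibble with genotype-based and clinical labels), `matches`,
#'   `actionability`, `potentially_actionable`.
#' @export
#'
#' @examples
#' bundle <- load_reference_bundle()
#' p <- fixture_cohort_table3(bundle)[[9]]
#' interpret_patient(p, bundle)$phenotypes$clinical_phenotype
interpret_patient <- function(patient, bundle) {
  phenos <- call_phenotypes(patient$snp_calls, bundle)
  strength <- inhibitor_strength(patient$medications, bundle)
  clinical <- purrr::map_dfr(seq_len(nrow(phenos)), function(i) {
    phenoconvert(phenos[i, ], strength)
  })
  matches <- active_panel_drugs(patient$medications, bundle)
  actionability <- purrr::map_dfr(seq_len(nrow(matches)), function(i) {
    cp <- clinical$clinical_phenotype[clinical$gene == matches$gene[i]]
    classify_gene_drug_pair(matches[i, ], cp)
  })
  if (nrow(actionability) == 0) {
    actionability <- tibble(drug = character(0), gene = character(0),
                            clinical_phenotype = character(0),
                            currently_actionable = logical(0),
                            future_watch = logical(0),
                            evidence_grade = character(0))
  }
  potential <- potentially_actionable_profile(
    clinical |> select("gene", "genotype_based_phenotype"), bundle
  )
  list(
    sample_id = patient$sample_id,
    inhibitor_strength = strength,
    phenotypes = clinical,
    matches = matches |> select("drug", "gene", "route", "evidence_grade"),
    actionability = actionability |>
      mutate(sample_id = patient$sample_id, .before = 1),
    potentially_actionable = potential
  )
}

#' Interpret every patient of a cohort
#'
#' @param cohort List of `pgx_patient` records.
#' @param bundle Reference bundle.
#' @return List of [interpret_patient()] results.
#' @export
interpret_cohort <- function(cohort, bundle = load_reference_bundle()) {
  map(cohort, interpret_patient, bundle = bundle)
}

#' Assemble the cohort-level descriptive report
#'
#' Produces the pilot-style analytics from interpreted patients plus the
#' funnel, survey and demographics tables: per-gene phenotype frequency
#' tables, the CYP2D6 phenoconversion summary, the gene-drug actionability
#' summary, demographics, funnel stage rates and survey fractions.
#'
#' @param results List of [interpret_patient()] results.
#' @param funnel Funnel record tibble (optional).
#' @param survey Survey response tibble (optional).
#' @param demographics Demographics tibble (optional).
#' @param bundle Reference bundle.
#' @return Nested list with elements `actionability`, `demographics`,
#'   `frequency_tables`, `funnel`, `n_patients`,
#'   `n_potentially_actionable`, `phenoconversion`, `survey`.
#' @export
cohort_report <- function(results, funnel = NULL, survey = NULL,
                          demographics = NULL,
                          bundle = load_reference_bundle()) {
  phenos <- purrr::map_dfr(results, "phenotypes")
  freq_tables <- map(stats::setNames(PANEL_GENES, PANEL_GENES), function(g) {
    phenotype_frequency_table(phenos |> filter(.data$gene == g), g)
  })
  cyp2d6 <- phenos |> filter(.data$gene == "CYP2D6")
  action_calls <- purrr::map_dfr(results, "actionability")
  report <- list(
    actionability = actionability_summary(action_calls, bundle),
    demographics = if (!is.null(demographics)) {
      demographics_summary(demographics)
    },
    frequency_tables = freq_tables,
    funnel = if (!is.null(funnel)) funnel_summary(funnel),
    n_patients = length(results),
    n_potentially_actionable = sum(map_lgl(
      results, ~ .x$potentially_actionable$actionable
    )),
    phenoconversion = phenoconversion_summary(cyp2d6),
    survey = if (!is.null(survey)) survey_summary(survey)
  )
  report[!vapply(report, is.null, logical(1))]
}
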