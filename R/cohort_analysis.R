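#' Phenotype frequency table for one gene
#'
#' Counts phenotype labels (including `indeterminate`) over a cohort's calls
#' for one gene. Percentages follow the cohort-table convention: arithmetic
#' half-up rounding to a whole percent, with one decimal kept for fractions
#' below 5%.
#'
#' @param calls Tibble of phenotype calls (all for the same gene).
#' @param gene Gene symbol; must match every row of `calls`.
#' @param label_col Column holding the label to tabulate
#'   (`"genotype_based_phenotype"` by default; use `"clinical_phenotype"` for
#'   post-phenoconversion tables).
#' @return Tibble with columns `gene`, `label`, `count`, `percent`, `n_total`.
#' @export
phenotype_frequency_table <- function(calls, gene,
                                      label_col = "genotype_based_phenotype") {
  if (nrow(calls) == 0) {
    return(tibble(gene = character(0), label = character(0),
                  count = integer(0), percent = numeric(0),
                  n_total = integer(0)))
  }
  if (!all(calls$gene == gene)) {
    abort(sprintf("calls mix genes; expected only %s", gene),
          class = "pgx_input_error")
  }
  n_total <- nrow(calls)
  labels <- calls[[label_col]]
  tab <- tibble(label = labels) |>
    count(.data$label, name = "count") |>
    mutate(
      gene = gene,
      percent = format_percent(.data$count, n_total),
      n_total = n_total,
      rank = phenotype_rank(.data$label)
    ) |>
    arrange(.data$rank, .data$label) |>
    select("gene", "label", "count", "percent", "n_total")
  tab
}

#' Summarize CYP2D6 phenoconversion over a cohort
#'
#' @param clinical_calls Tibble of CYP2D6 clinical phenotype calls (output of
#'   [phenoconvert()], one row per patient).
#' @return List: `n`, `n_exposed` (inhibitor strength not `"none"`),
#'   `n_converted`, `genotype_counts` and `clinical_counts` frequency tables,
#'   and poor-metabolizer prevalence before/after phenoconversion (percent,
#'   half-up; one decimal below 5%).
#' @export
phenoconversion_summary <- function(clinical_calls) {
  if (nrow(clinical_calls) > 0 && !all(clinical_calls$gene == "CYP2D6")) {
    abort("phenoconversion summaries are defined for CYP2D6 calls only",
          class = "pgx_input_error")
  }
  n <- nrow(clinical_calls)
  pm_pct <- function(col) {
    if (n == 0) return(NA_real_)
    format_percent(sum(clinical_calls[[col]] == "PM"), n)
  }
  list(
    n = n,
    n_exposed = sum(clinical_calls$inhibitor_strength_applied != "none"),
    n_converted = sum(clinical_calls$phenoconverted),
    genotype_counts = phenotype_frequency_table(clinical_calls, "CYP2D6"),
    clinical_counts = phenotype_frequency_table(clinical_calls, "CYP2D6",
                                                label_col = "clinical_phenotype"),
    pm_prevalence_before = pm_pct("genotype_based_phenotype"),
    pm_prevalence_after = pm_pct("clinical_phenotype")
  )
}

#' Summarize gene-drug actionability over a cohort
#'
#' @param cohort_calls List of per-patient actionability tibbles (output of
#'   [classify_gene_drug_pair()] rows), or one tibble with a `sample_id`
#'   column.
#' @param bundle Reference bundle (supplies the drug-class map).
#' @return List: `total_active_panel_drugs` (distinct active panel-drug
#'   prescriptions), `n_pairs`, `n_actionable_pairs`,
#'   `n_actionable_moderate_plus` (actionable pairs with at least moderate
#'   evidence), `by_class` and `per_drug` count tables.
#' @export
actionability_summary <- function(cohort_calls, bundle) {
  calls <- if (is.data.frame(cohort_calls)) {
    cohort_calls
  } else {
    bound <- bind_rows(cohort_calls, .id = "patient_index")
    if (!"sample_id" %in% names(bound)) {
      bound$sample_id <- if ("patient_index" %in% names(bound)) {
        bound$patient_index
      } else {
        character(0)
      }
    }
    bound
  }
  if (nrow(calls) == 0) {
    return(list(total_active_panel_drugs = 0L, n_pairs = 0L,
                n_actionable_pairs = 0L, n_actionable_moderate_plus = 0L,
                by_class = tibble(class = character(0), n_pairs = integer(0),
                                  n_actionable = integer(0)),
                per_drug = tibble(drug = character(0), n_pairs = integer(0),
                                  n_actionable = integer(0))))
  }
  # one pair per (patient, drug, gene): no double counting within a patient
  calls <- calls |> distinct(.data$sample_id, .data$drug, .data$gene,
                             .keep_all = TRUE)
  with_class <- calls |>
    left_join(bundle$drug_classes, by = "drug") |>
    mutate(class = ifelse(is.na(.data$class), "other", .data$class))
  list(
    total_active_panel_drugs = nrow(distinct(calls, .data$sample_id, .data$drug)),
    n_pairs = nrow(calls),
    n_actionable_pairs = sum(calls$currently_actionable),
    n_actionable_moderate_plus = sum(calls$currently_actionable &
                                       calls$evidence_grade %in%
                                       c("strong", "moderate")),
    by_class = with_class |>
      group_by(.data$class) |>
      summarise(n_pairs = n(),
                n_actionable = sum(.data$currently_actionable),
                .groups = "drop"),
    per_drug = with_class |>
      group_by(.data$drug) |>
      summarise(n_pairs = n(),
                n_actionable = sum(.data$currently_actionable),
                .groups = "drop") |>
      arrange(desc(.data$n_pairs), .data$drug)
  )
}

#' Demographic summary of a cohort
#'
#' @param patients Tibble with columns `age`, `sex`, `race`, `ethnicity`.
#' @return List: `n`; `age` (min, mean, sd with the sample n-1 convention,
#'   max); `sex`, `race`, `ethnicity` count tables with percents rounded
#'   half-up to one decimal.
#' @export
demographics_summary <- function(patients) {
  if (nrow(patients) == 0) {
    abort("cannot summarise an empty cohort", class = "pgx_input_error")
  }
  if (any(patients$age <= 0)) {
    abort("ages must be positive", class = "pgx_input_error")
  }
  breakdown <- function(col) {
    patients |>
      count(label = .data[[col]], name = "count") |>
      mutate(percent = round_half_up(100 * .data$count / nrow(patients), 1)) |>
      arrange(desc(.data$count), .data$label)
  }
  list(
    n = nrow(patients),
    age = list(min = min(patients$age),
               mean = mean(patients$age),
               sd = stats::sd(patients$age),
               max = max(patients$age)),
    sex = breakdown("sex"),
    race = breakdown("race"),
    ethnicity = breakdown("ethnicity")
  )
}

validate_funnel <- function(records) {
  stages <- c("identified", "contacted", "confirmed_eligible", "agreed",
              "kit_returned")
  m <- vapply(stages, function(s) as.logical(records[[s]]),
              logical(nrow(records)))
  m <- matrix(m, nrow = nrow(records))
  bad <- rep(FALSE, nrow(records))
  for (k in seq_len(length(stages) - 1)) {
    bad <- bad | (m[, k + 1] & !m[, k])  # later stage reached, earlier skipped
  }
  if (any(bad)) {
    abort(sprintf("funnel record(s) violate stage monotonicity: %s",
                  paste(utils::head(records$sample_id[bad], 5), collapse = ", ")),
          class = "pgx_input_error")
  }
  invisible(records)
}

#' Summarize an enrollment funnel
#'
#' Stage counts with whole-percent rates: contact rate = contacted/identified,
#' consent rate = agreed/confirmed eligible, kit-return rate =
#' returned/agreed; plus consent-channel and exclusion-reason breakdowns and
#' the mailing-to-result turnaround mean and sample SD.
#'
#' @param records Funnel record tibble (see [fixture_funnel_fig2()] for the
#'   schema). Stage outcomes must be monotone: a later stage implies all
#'   earlier ones.
#' @return List: `counts`, `rates` (whole percents, half-up), `channels`,
#'   `exclusions`, `turnaround` (mean, sd, n).
#' @export
funnel_summary <- function(records) {
  validate_funnel(records)
  counts <- list(
    identified = sum(records$identified),
    contacted = sum(records$contacted),
    excluded_at_contact = sum(records$contacted & !records$confirmed_eligible),
    confirmed_eligible = sum(records$confirmed_eligible),
    agreed = sum(records$agreed),
    kit_returned = sum(records$kit_returned)
  )
  rate <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 0)
  }
  tt <- records$turnaround_days[records$kit_returned &
                                  !is.na(records$turnaround_days)]
  list(
    counts = counts,
    rates = list(
      contact = rate(counts$contacted, counts$identified),
      consent = rate(counts$agreed, counts$confirmed_eligible),
      kit_return = rate(counts$kit_returned, counts$agreed)
    ),
    channels = records |>
      filter(.data$agreed) |>
      count(channel = .data$consent_channel, name = "count") |>
      mutate(percent = round_half_up(100 * .data$count / counts$agreed, 0)),
    exclusions = records |>
      filter(.data$contacted, !.data$confirmed_eligible) |>
      count(reason = .data$exclusion_reason, name = "count"),
    turnaround = list(mean = if (length(tt)) mean(tt) else NA_real_,
                      sd = if (length(tt) > 1) stats::sd(tt) else NA_real_,
                      n = length(tt))
  )
}

#' Summarize post-test survey responses
#'
#' @param responses Tibble with logical columns `overall_positive`,
#'   `prefers_specialist`, `perceived_impact`.
#' @return List: `n_responders` and whole-percent (half-up) fractions for
#'   each question; percents are `NA` when there are no responders.
#' @export
survey_summary <- function(responses) {
  n <- nrow(responses)
  pct <- function(col) {
    if (n == 0) return(NA_real_)
    round_half_up(100 * sum(responses[[col]]) / n, 0)
  }
  list(
    n_responders = n,
    pct_overall_positive = pct("overall_positive"),
    pct_prefers_specialist = pct("prefers_specialist"),
    pct_perceived_impact = pct("perceived_impact")
  )
}
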