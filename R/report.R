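RECOMMENDATION_TEXT <- c(
  actionable = "ACTIONABLE - consider alternative agent or dose adjustment per guideline",
  future = "no change currently recommended; may become actionable in the future based on indication",
  none = "no change recommended"
)

#' Render a pharmacist-style consult note
#'
#' Deterministic plain-text note from one patient's interpretation: per-gene
#' genotype/phenotype lines, a phenoconversion caveat when the clinical
#' CYP2D6 phenotype differs from the genotype-based one, interpretations for
#' every active panel-drug pair (each actionable pair appears exactly once,
#' with its recommendation category and evidence grade), future-relevance
#' statements for potentially actionable genes, and a retest note for
#' indeterminate genes.
#'
#' @param result An [interpret_patient()] result; all eight panel genes must
#'   be present.
#' @return Note text (single string).
#' @export
#'
#' @examples
#' bundle <- load_reference_bundle()
#' p <- fixture_cohort_table3(bundle)[[9]]
#' cat(render_consult_note(interpret_patient(p, bundle)))
render_consult_note <- function(result) {
  phen <- result$phenotypes
  missing <- setdiff(PANEL_GENES, phen$gene)
  if (length(missing) > 0) {
    abort(sprintf("interpretation incomplete; missing gene(s): %s",
                  paste(missing, collapse = ", ")),
          class = "pgx_input_error")
  }
  lines <- c(
    sprintf("PHARMACOGENETIC CONSULT NOTE - sample %s", result$sample_id),
    "",
    "Genotype/phenotype summary:"
  )
  for (i in seq_len(nrow(phen))) {
    r <- phen[i, ]
    dip <- if (is.na(r$diplotype)) "indeterminate" else r$diplotype
    line <- sprintf("  %s: %s - %s", r$gene, dip, r$genotype_based_phenotype)
    if (r$gene == "CYP2D6" &&
        !identical(r$clinical_phenotype, r$genotype_based_phenotype)) {
      line <- sprintf("%s; clinical phenotype %s (%s CYP2D6 inhibitor on active medication list)",
                      line, r$clinical_phenotype, r$inhibitor_strength_applied)
    }
    lines <- c(lines, line)
  }

  converted <- phen |> filter(.data$gene == "CYP2D6", .data$phenoconverted)
  if (nrow(converted) == 1) {
    lines <- c(lines, "",
               sprintf("Phenoconversion: a %s CYP2D6 inhibitor converts this patient's genotype-based %s status to a clinical %s; recommendations below use the clinical phenotype.",
                       converted$inhibitor_strength_applied,
                       converted$genotype_based_phenotype,
                       converted$clinical_phenotype))
  }

  lines <- c(lines, "", "Current medications (active panel drugs):")
  act <- result$actionability
  if (nrow(act) == 0) {
    lines <- c(lines, "  none with panel gene associations")
  } else {
    for (i in seq_len(nrow(act))) {
      a <- act[i, ]
      rec <- if (a$currently_actionable) {
        sprintf("%s (evidence: %s)", RECOMMENDATION_TEXT[["actionable"]],
                a$evidence_grade)
      } else if (a$future_watch) {
        RECOMMENDATION_TEXT[["future"]]
      } else {
        RECOMMENDATION_TEXT[["none"]]
      }
      lines <- c(lines, sprintf("  %s (%s, clinical phenotype %s): %s",
                                a$drug, a$gene, a$clinical_phenotype, rec))
    }
  }

  pot <- result$potentially_actionable
  lines <- c(lines, "", if (pot$actionable) {
    sprintf("Future medication relevance: genotype-based phenotype(s) in %s would trigger guideline recommendations for panel drugs if such therapy is initiated.",
            paste(pot$genes, collapse = ", "))
  } else {
    "Future medication relevance: no potentially actionable phenotypes identified among panel genes."
  })

  indet <- phen |> filter(.data$genotype_based_phenotype == "indeterminate")
  if (nrow(indet) > 0) {
    lines <- c(lines,
               sprintf("Indeterminate result for %s: genotype could not be resolved; consider retesting with an orthogonal assay.",
                       paste(indet$gene, collapse = ", ")))
  }
  paste(lines, collapse = "\n")
}

# jsonlite writer with the package's conventions: UTF-8, unboxed scalars,
# full precision, data frames as row records.
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

serialize_patient_result <- function(result) {
  list(
    sample_id = result$sample_id,
    inhibitor_strength = result$inhibitor_strength,
    phenotypes = result$phenotypes,
    matches = result$matches,
    actionability = result$actionability,
    potentially_actionable = result$potentially_actionable
  )
}

read_config <- function(config) {
  if (is.list(config)) return(config)
  assert_file_exists(config, "config")
  if (grepl("\\.ya?ml$", config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("YAML configs require the yaml package", class = "pgx_config_error")
    }
    yaml::read_yaml(config)
  } else {
    jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
}

#' Run a pipeline stage against input/output directories
#'
#' Thin orchestration layer over the package's functions, mirroring the
#' command-line interface:
#' \describe{
#'   \item{fixtures}{write the deterministic fixture cohort, funnel and
#'     survey files to `out_dir`.}
#'   \item{interpret}{read genotypes/cnv/medications from `in_dir`, interpret
#'     every patient, write `patients.json` and one consult note per patient
#'     under `notes/`.}
#'   \item{cohort}{read `patients.json` plus funnel/survey/demographics files
#'     from `in_dir`, write `cohort_report.json` and TSV tables under
#'     `tables/`.}
#'   \item{simulate}{generate a stochastic cohort and funnel (honouring
#'     `seed`, `n`) and write their input files to `out_dir`.}
#' }
#'
#' @param command One of `"fixtures"`, `"interpret"`, `"cohort"`,
#'   `"simulate"`.
#' @param config List (or path to a JSON/YAML file) with fields `in_dir`,
#'   `out_dir` and, for simulate, `seed` and `n`.
#' @param bundle Reference bundle.
#' @return Invisibly, a list of the output paths written.
#' @export
run_pipeline <- function(command = c("fixtures", "interpret", "cohort",
                                     "simulate"),
                         config = list(), bundle = load_reference_bundle()) {
  command <- match.arg(command)
  cfg <- read_config(config)
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (command == "fixtures") {
    cohort <- fixture_cohort_table3(bundle)
    write_cohort_files(cohort, out_dir)
    readr::write_csv(fixture_funnel_fig2(), file.path(out_dir, "funnel.csv"))
    readr::write_csv(fixture_survey_fig5(), file.path(out_dir, "survey.csv"))
    message(sprintf("fixtures: %d patients, 244 funnel records, 24 survey responses -> %s",
                    length(cohort), out_dir))
    return(invisible(list(out_dir = out_dir)))
  }

  if (command == "simulate") {
    params <- cohort_params(n = cfg$n %||% 61, seed = cfg$seed %||% 1L)
    cohort <- simulate_cohort(params, bundle)
    write_cohort_files(cohort, out_dir)
    fp <- funnel_params(seed = cfg$seed %||% 1L)
    readr::write_csv(simulate_funnel(fp), file.path(out_dir, "funnel.csv"))
    message(sprintf("simulate: %d patients (seed %s) -> %s",
                    length(cohort), params$seed, out_dir))
    return(invisible(list(out_dir = out_dir)))
  }

  in_dir <- cfg$in_dir %||% out_dir

  if (command == "interpret") {
    cohort <- read_cohort_files(in_dir)
    results <- interpret_cohort(cohort, bundle)
    patients_path <- file.path(out_dir, "patients.json")
    write_report_json(map(results, serialize_patient_result), patients_path)
    notes_dir <- file.path(out_dir, "notes")
    dir.create(notes_dir, showWarnings = FALSE)
    note_paths <- map_chr(results, function(r) {
      p <- file.path(notes_dir, paste0(r$sample_id, ".txt"))
      writeLines(render_consult_note(r), p)
      p
    })
    message(sprintf("interpret: %d patients, %d actionable pairs -> %s",
                    length(results),
                    sum(purrr::map_int(results,
                                       ~ sum(.x$actionability$currently_actionable))),
                    patients_path))
    return(invisible(list(patients = patients_path, notes = note_paths)))
  }

  # command == "cohort": recompute summaries from the interpret stage output
  patients_path <- file.path(in_dir, "patients.json")
  assert_file_exists(patients_path, "patients.json")
  raw <- jsonlite::fromJSON(patients_path, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  results <- map(seq_len(nrow(raw)), function(i) {
    list(
      sample_id = raw$sample_id[i],
      inhibitor_strength = raw$inhibitor_strength[i],
      phenotypes = as_tibble(raw$phenotypes[[i]]),
      actionability = as_tibble(raw$actionability[[i]]),
      potentially_actionable = list(
        actionable = isTRUE(raw$potentially_actionable$actionable[i]),
        genes = raw$potentially_actionable$genes[[i]]
      )
    )
  })
  maybe_read <- function(file, reader) {
    p <- file.path(in_dir, file)
    if (file.exists(p)) reader(p) else NULL
  }
  report <- cohort_report(
    results,
    funnel = maybe_read("funnel.csv", read_funnel),
    survey = maybe_read("survey.csv", read_survey),
    demographics = maybe_read("demographics.csv", read_demographics),
    bundle = bundle
  )
  report_path <- file.path(out_dir, "cohort_report.json")
  write_report_json(report, report_path)
  tables_dir <- file.path(out_dir, "tables")
  dir.create(tables_dir, showWarnings = FALSE)
  bind_rows(report$frequency_tables) |>
    readr::write_tsv(file.path(tables_dir, "phenotype_frequencies.tsv"))
  if (!is.null(report$demographics)) {
    bind_rows(
      report$demographics$sex |> mutate(variable = "sex"),
      report$demographics$race |> mutate(variable = "race"),
      report$demographics$ethnicity |> mutate(variable = "ethnicity")
    ) |>
      readr::write_tsv(file.path(tables_dir, "demographics.tsv"))
  }
  message(sprintf("cohort: report for %d patients -> %s",
                  report$n_patients, report_path))
  invisible(list(report = report_path, tables = tables_dir))
}
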