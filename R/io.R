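# Readers for the pipeline's standard input files.

#' Read rsID-level genotype calls
#'
#' @param path genotypes.tsv with columns sample_id, rsid, allele_1, allele_2.
#' @return Tibble of calls.
#' @export
read_genotypes <- function(path) {
  assert_file_exists(path, "genotype")
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("sample_id", "rsid", "allele_1", "allele_2")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("genotypes (%s): missing column(s) %s", path,
                  paste(missing, collapse = ", ")),
          class = "pgx_parse_error")
  }
  if (nrow(tbl) == 0) {
    abort(sprintf("genotypes (%s): no rows", path), class = "pgx_parse_error")
  }
  tbl
}

#' Read CYP2D6 copy-number flags
#'
#' @param path cnv.tsv with columns sample_id, cyp2d6_cnv (yes/no/unknown).
#' @return Tibble of flags.
#' @export
read_cnv <- function(path) {
  assert_file_exists(path, "CNV flag")
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

#' Read a medication list
#'
#' @param path medications.csv with columns sample_id, drug, route, active.
#' @return Tibble of medication records.
#' @export
read_medications <- function(path) {
  assert_file_exists(path, "medication")
  readr::read_csv(path, col_types = readr::cols(active = "l", .default = "c"),
                  progress = FALSE)
}

#' Read demographics
#'
#' @param path demographics.csv with columns sample_id, age, sex, race,
#'   ethnicity.
#' @return Tibble of demographics.
#' @export
read_demographics <- function(path) {
  assert_file_exists(path, "demographics")
  readr::read_csv(path, col_types = readr::cols(age = "d", .default = "c"),
                  progress = FALSE)
}

#' Read enrollment funnel records
#'
#' @param path funnel.csv (schema of [fixture_funnel_fig2()]).
#' @return Tibble of funnel records.
#' @export
read_funnel <- function(path) {
  assert_file_exists(path, "funnel")
  readr::read_csv(
    path,
    col_types = readr::cols(identified = "l", contacted = "l",
                            confirmed_eligible = "l", agreed = "l",
                            kit_returned = "l", turnaround_days = "d",
                            .default = "c"),
    progress = FALSE
  )
}

#' Read survey responses
#'
#' @param path survey.csv (schema of [fixture_survey_fig5()]).
#' @return Tibble of survey responses.
#' @export
read_survey <- function(path) {
  assert_file_exists(path, "survey")
  readr::read_csv(
    path,
    col_types = readr::cols(overall_positive = "l", prefers_specialist = "l",
                            perceived_impact = "l", .default = "c"),
    progress = FALSE
  )
}

#' Assemble per-sample call sets from genotype and CNV tables
#'
#' @param genotypes Tibble from [read_genotypes()].
#' @param cnv Tibble from [read_cnv()] (samples absent get flag "unknown").
#' @return Named list of `pgx_snp_calls`, one per sample.
#' @export
build_call_sets <- function(genotypes, cnv = NULL) {
  cnv_map <- if (!is.null(cnv)) {
    stats::setNames(cnv$cyp2d6_cnv, cnv$sample_id)
  } else {
    character(0)
  }
  samples <- unique(genotypes$sample_id)
  out <- map(samples, function(s) {
    rows <- genotypes |> filter(.data$sample_id == s)
    calls <- map2(rows$allele_1, rows$allele_2, c)
    names(calls) <- rows$rsid
    snp_call_set(s, calls,
                 cyp2d6_cnv = unname(cnv_map[s] %|na|% "unknown"))
  })
  stats::setNames(out, samples)
}

`%|na|%` <- function(x, default) {
  if (length(x) == 0 || is.na(x)) default else x
}

#' Read genotype calls from a VCF keyed on rsID
#'
#' Optional ingestion path: sites are matched by the VCF ID field and the
#' genotype is taken from the named sample's GT, assumed unphased. Requires
#' the vcfR package.
#'
#' @param path VCF file path.
#' @param sample_id Sample column to extract (defaults to the first).
#' @return Tibble in the [read_genotypes()] schema.
#' @export
read_genotypes_vcf <- function(path, sample_id = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF ingestion requires the vcfR package", class = "pgx_config_error")
  }
  assert_file_exists(path, "VCF")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gts <- vcfR::extract.gt(vcf, element = "GT")
  sample_id <- sample_id %||% colnames(gts)[1]
  if (!sample_id %in% colnames(gts)) {
    abort(sprintf("sample %s not present in VCF", sample_id),
          class = "pgx_input_error")
  }
  gt <- gts[, sample_id]
  alleles_at <- function(i) {
    opts <- c(fix$REF[i], str_split(fix$ALT[i], ",")[[1]])
    code <- gt[i]
    if (is.na(code)) return(c("missing", "missing"))
    idx <- suppressWarnings(as.integer(str_split(code, "[/|]")[[1]]))
    if (length(idx) != 2 || any(is.na(idx))) return(c("missing", "missing"))
    opts[idx + 1]
  }
  purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    pair <- alleles_at(i)
    tibble(sample_id = sample_id, rsid = fix$ID[i],
           allele_1 = pair[1], allele_2 = pair[2])
  }) |>
    filter(!is.na(.data$rsid), .data$rsid != ".")
}

#' Assemble a cohort of patient records from the standard input files
#'
#' @param dir Directory containing genotypes.tsv, cnv.tsv, medications.csv
#'   and (optionally) demographics.csv.
#' @return List of `pgx_patient` records.
#' @export
read_cohort_files <- function(dir) {
  genotypes <- read_genotypes(file.path(dir, "genotypes.tsv"))
  cnv <- read_cnv(file.path(dir, "cnv.tsv"))
  meds <- read_medications(file.path(dir, "medications.csv"))
  demo_path <- file.path(dir, "demographics.csv")
  demo <- if (file.exists(demo_path)) read_demographics(demo_path) else NULL
  call_sets <- build_call_sets(genotypes, cnv)
  map(names(call_sets), function(s) {
    m <- meds |> filter(.data$sample_id == s)
    structure(
      list(sample_id = s,
           snp_calls = call_sets[[s]],
           medications = if (nrow(m) > 0) {
             medication_record(m$drug, m$route, m$active)
           } else {
             empty_medications()
           },
           demographics = if (!is.null(demo)) {
             demo |> filter(.data$sample_id == s)
           }),
      class = "pgx_patient"
    )
  })
}
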