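#' Path to the shipped reference tables
#'
#' Returns the directory containing the curated default reference tables:
#' star-allele definitions for the 8-gene panel, CYP2D6 inhibitor strengths,
#' the 27-drug panel/actionability rules, the legacy CYP2D6 activity-score
#' cutoff map, and the drug-class map used by cohort summaries.
#'
#' @return Directory path as a string.
#' @export
pgx_reference_dir <- function() {
  system.file("extdata", "reference", package = "pgxpanel", mustWork = TRUE)
}

ref_path <- function(file) file.path(pgx_reference_dir(), file)

read_ref_tsv <- function(path, required_cols, what) {
  assert_file_exists(path, what)
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(required_cols, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("%s (%s): missing column(s) %s",
                  what, path, paste(missing, collapse = ", ")),
          class = "pgx_parse_error")
  }
  tbl
}

# "rs123=A;rs456=T" -> named character vector c(rs123 = "A", rs456 = "T").
parse_rsid_list <- function(x, path, line) {
  if (is.na(x) || x == "") return(stats::setNames(character(0), character(0)))
  parts <- str_split(x, ";")[[1]]
  kv <- str_split(parts, "=")
  bad <- map_lgl(kv, ~ length(.x) != 2 || any(.x == ""))
  if (any(bad)) {
    abort(sprintf("allele definitions (%s), line %d, field rsid_list: expected rsID=allele pairs, got '%s'",
                  path, line, x),
          class = "pgx_parse_error")
  }
  stats::setNames(map_chr(kv, 2), map_chr(kv, 1))
}

split_set <- function(x) {
  if (is.na(x) || str_trim(x) == "") return(character(0))
  str_trim(str_split(x, ";")[[1]])
}

# CYP2C9 activity-score map (the panel's fixed convention: scores below 1
# are poor metabolizers, 1 to below 2 intermediate, 2 and above normal).
cyp2c9_cutoff_map <- function() {
  tibble(lower = c(0, 1, 2), upper = c(1, 2, Inf), label = c("PM", "IM", "NM"))
}

read_cutoff_map <- function(path) {
  assert_file_exists(path, "cutoff map")
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!all(c("lower", "upper", "label") %in% names(raw))) {
    abort(sprintf("cutoff map (%s): expected fields lower, upper, label", path),
          class = "pgx_parse_error")
  }
  tibble(lower = as.numeric(raw$lower),
         upper = ifelse(is.na(raw$upper), Inf, as.numeric(raw$upper)),
         label = as.character(raw$label)) |>
    arrange(.data$lower)
}

# Diplotype -> phenotype lookups derived from allele function classes, per
# CPIC translation conventions:
#  * CYP2C19: no/no = PM, no/normal = IM, no/increased = IM,
#    normal/normal = NM, normal/increased = RM, increased/increased = UM
#  * CYP3A5: any normal-function (expresser) allele = NM, else PM
#  * SLCO1B1: normal/normal = normal function, normal/decreased = decreased
#    function, decreased/decreased = poor function
make_phenotype_lookup <- function(alleles) {
  lookup_for_gene <- function(gene, label_fun) {
    al <- alleles |> filter(.data$gene == !!gene)
    pairs <- expand.grid(i = seq_len(nrow(al)), j = seq_len(nrow(al)))
    pairs <- pairs[pairs$i <= pairs$j, , drop = FALSE]
    tibble(
      gene = gene,
      diplotype = map2_chr(pairs$i, pairs$j, function(i, j) {
        paste(sort_alleles(al$star_allele[i], al$star_allele[j]),
              collapse = "/")
      }),
      phenotype = map2_chr(pairs$i, pairs$j, function(i, j) {
        label_fun(al$function_class[i], al$function_class[j])
      })
    )
  }
  c19 <- function(f1, f2) {
    fs <- sort(c(f1, f2))
    if (identical(fs, c("no", "no"))) "PM"
    else if ("no" %in% fs) "IM"
    else if (identical(fs, c("normal", "normal"))) "NM"
    else if (identical(fs, c("increased", "normal"))) "RM"
    else "UM"
  }
  c3a5 <- function(f1, f2) if ("normal" %in% c(f1, f2)) "NM" else "PM"
  slco <- function(f1, f2) {
    n_dec <- sum(c(f1, f2) == "decreased")
    c("normal function", "decreased function", "poor function")[n_dec + 1]
  }
  bind_rows(
    lookup_for_gene("CYP2C19", c19),
    lookup_for_gene("CYP3A5", c3a5),
    lookup_for_gene("SLCO1B1", slco)
  )
}

#' Load and validate the pipeline's reference bundle
#'
#' Reads the allele-definition, inhibitor and panel-drug tables (TSV) plus the
#' legacy CYP2D6 activity-score cutoff map (JSON) and assembles the validated
#' bundle every downstream module consumes. All arguments default to the
#' tables shipped with the package.
#'
#' @param allele_path Path to allele_definitions.tsv (columns gene,
#'   star_allele, rsid_list as semicolon-joined `rsID=allele` pairs,
#'   activity_value, function_class).
#' @param inhibitor_path Path to inhibitors.tsv (columns drug, gene, strength).
#' @param panel_path Path to panel_drugs.tsv (columns drug, gene,
#'   actionable_phenotypes, future_watch_phenotypes, evidence_grade,
#'   eligible_routes, synonyms; set-valued columns semicolon-joined).
#' @param cutoff_path Path to cutoffs.json, a list of half-open
#'   `{lower, upper, label}` activity-score intervals for CYP2D6 (null upper
#'   means unbounded).
#' @param class_path Path to drug_classes.tsv (columns drug, class).
#'
#' @return A list of class `pgx_reference` with elements `alleles`,
#'   `inhibitors`, `panel_rules`, `cyp2d6_cutoffs`, `cyp2c9_cutoffs`,
#'   `phenotype_lookup`, `drug_classes` and `synonym_map`.
#' @export
#'
#' @examples
#' bundle <- load_reference_bundle()
#' length(unique(bundle$panel_rules$drug))  # 27 panel drugs
load_reference_bundle <- function(allele_path = ref_path("allele_definitions.tsv"),
                                  inhibitor_path = ref_path("inhibitors.tsv"),
                                  panel_path = ref_path("panel_drugs.tsv"),
                                  cutoff_path = ref_path("cutoffs.json"),
                                  class_path = ref_path("drug_classes.tsv")) {
  al_raw <- read_ref_tsv(allele_path,
                         c("gene", "star_allele", "rsid_list",
                           "activity_value", "function_class"),
                         "allele definitions")
  alleles <- al_raw |>
    mutate(
      rsid_list = ifelse(is.na(.data$rsid_list), "", .data$rsid_list),
      variants = map(seq_len(n()), function(i) {
        parse_rsid_list(al_raw$rsid_list[i], allele_path, i + 1L)
      }),
      activity_value = suppressWarnings(as.numeric(.data$activity_value))
    ) |>
    select("gene", "star_allele", "variants", "activity_value",
           "function_class")

  inhibitors <- read_ref_tsv(inhibitor_path, c("drug", "gene", "strength"),
                             "inhibitor table") |>
    mutate(drug = tolower(.data$drug))

  pd_raw <- read_ref_tsv(panel_path,
                         c("drug", "gene", "actionable_phenotypes",
                           "future_watch_phenotypes", "evidence_grade",
                           "eligible_routes"),
                         "panel drug table")
  panel_rules <- pd_raw |>
    mutate(
      drug = tolower(.data$drug),
      actionable_phenotypes = map(.data$actionable_phenotypes, split_set),
      future_watch_phenotypes = map(.data$future_watch_phenotypes, split_set),
      eligible_routes = map(.data$eligible_routes, split_set),
      synonyms = if ("synonyms" %in% names(pd_raw)) {
        map(.data$synonyms, split_set)
      } else {
        map(seq_len(n()), ~ character(0))
      }
    )

  drug_classes <- read_ref_tsv(class_path, c("drug", "class"), "drug classes") |>
    mutate(drug = tolower(.data$drug))

  syn_pairs <- panel_rules |>
    select("drug", "synonyms") |>
    tidyr::unnest_longer("synonyms", values_to = "synonym") |>
    filter(!is.na(.data$synonym), .data$synonym != "") |>
    distinct(.data$synonym, .data$drug)
  synonym_map <- stats::setNames(syn_pairs$drug, tolower(syn_pairs$synonym))

  bundle <- structure(
    list(
      alleles = alleles,
      inhibitors = inhibitors,
      panel_rules = panel_rules,
      cyp2d6_cutoffs = read_cutoff_map(cutoff_path),
      cyp2c9_cutoffs = cyp2c9_cutoff_map(),
      phenotype_lookup = make_phenotype_lookup(alleles),
      drug_classes = drug_classes,
      synonym_map = synonym_map
    ),
    class = "pgx_reference"
  )

  violations <- validate_reference(bundle)
  if (length(violations) > 0) {
    abort(paste0("reference bundle failed validation:\n",
                 paste0("  - ", violations, collapse = "\n")),
          class = "pgx_validation_error")
  }
  bundle
}

#' Check a reference bundle against its structural invariants
#'
#' Violations are returned as data, not raised: an empty character vector
#' means the bundle is internally consistent. Each violation names the table
#' and rule breached (and the row where identifiable).
#'
#' @param bundle A `pgx_reference` bundle (see [load_reference_bundle()]).
#' @return Character vector of violation descriptions; empty if valid.
#' @export
validate_reference <- function(bundle) {
  v <- character(0)
  al <- bundle$alleles

  dup <- al |> count(.data$gene, .data$star_allele) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    v <- c(v, sprintf("allele_definitions: duplicate (gene, star_allele) %s",
                      paste(dup$gene, dup$star_allele, collapse = "; ")))
  }
  off <- setdiff(unique(al$gene), PANEL_GENES)
  if (length(off) > 0) {
    v <- c(v, sprintf("allele_definitions: gene not on 8-gene panel: %s",
                      paste(off, collapse = ", ")))
  }
  for (g in intersect(unique(al$gene), PANEL_GENES)) {
    refs <- al |> filter(.data$gene == g, lengths(.data$variants) == 0)
    if (nrow(refs) != 1) {
      v <- c(v, sprintf("allele_definitions: gene %s must have exactly one reference allele (empty rsid_list), found %d",
                        g, nrow(refs)))
    }
  }
  as_needed <- al |> filter(.data$gene %in% c("CYP2D6", "CYP2C9"),
                            is.na(.data$activity_value))
  if (nrow(as_needed) > 0) {
    v <- c(v, sprintf("allele_definitions: missing activity_value for %s",
                      paste(as_needed$gene, as_needed$star_allele,
                            collapse = "; ")))
  }
  neg <- al |> filter(!is.na(.data$activity_value), .data$activity_value < 0)
  if (nrow(neg) > 0) {
    v <- c(v, "allele_definitions: negative activity_value")
  }

  dup_inh <- bundle$inhibitors |> count(.data$drug, .data$gene) |>
    filter(.data$n > 1)
  if (nrow(dup_inh) > 0) {
    v <- c(v, sprintf("inhibitors: duplicate (drug, gene) rows: %s",
                      paste(dup_inh$drug, collapse = ", ")))
  }
  bad_strength <- setdiff(unique(bundle$inhibitors$strength),
                          c("strong", "moderate"))
  if (length(bad_strength) > 0) {
    v <- c(v, sprintf("inhibitors: unknown strength token(s): %s",
                      paste(bad_strength, collapse = ", ")))
  }

  pr <- bundle$panel_rules
  n_drugs <- length(unique(pr$drug))
  if (n_drugs != 27) {
    v <- c(v, sprintf("panel_drugs: expected exactly 27 distinct drugs, found %d",
                      n_drugs))
  }
  off_pr <- setdiff(unique(pr$gene), PANEL_GENES)
  if (length(off_pr) > 0) {
    v <- c(v, sprintf("panel_drugs: gene not on 8-gene panel: %s",
                      paste(off_pr, collapse = ", ")))
  }
  overlap <- map_lgl(seq_len(nrow(pr)), function(i) {
    length(intersect(pr$actionable_phenotypes[[i]],
                     pr$future_watch_phenotypes[[i]])) > 0
  })
  if (any(overlap)) {
    v <- c(v, sprintf("panel_drugs: actionable and future-watch sets overlap for %s",
                      paste(pr$drug[overlap], pr$gene[overlap], collapse = "; ")))
  }
  bad_grade <- setdiff(unique(pr$evidence_grade),
                       c("strong", "moderate", "optional"))
  if (length(bad_grade) > 0) {
    v <- c(v, sprintf("panel_drugs: unknown evidence_grade: %s",
                      paste(bad_grade, collapse = ", ")))
  }
  dup_pr <- pr |> count(.data$drug, .data$gene) |> filter(.data$n > 1)
  if (nrow(dup_pr) > 0) {
    v <- c(v, sprintf("panel_drugs: duplicate (drug, gene) rows: %s",
                      paste(dup_pr$drug, dup_pr$gene, collapse = "; ")))
  }

  v <- c(v, validate_cutoff_map(bundle$cyp2d6_cutoffs, "cyp2d6_cutoffs"))
  v <- c(v, validate_cutoff_map(bundle$cyp2c9_cutoffs, "cyp2c9_cutoffs"))

  if (length(v) == 0) {
    lbl <- cutoff_label(1.0, bundle$cyp2d6_cutoffs)
    if (!identical(lbl, "NM")) {
      v <- c(v, sprintf("cyp2d6_cutoffs: legacy scheme requires activity score 1.0 to map to NM, got %s",
                        lbl))
    }
  }
  v
}

# Intervals must partition [0, Inf) with no gap or overlap.
validate_cutoff_map <- function(cutoffs, table_name) {
  v <- character(0)
  cutoffs <- cutoffs |> arrange(.data$lower)
  if (nrow(cutoffs) == 0) return(sprintf("%s: empty cutoff map", table_name))
  if (cutoffs$lower[1] != 0) {
    v <- c(v, sprintf("%s: first interval must start at 0", table_name))
  }
  if (!is.infinite(cutoffs$upper[nrow(cutoffs)])) {
    v <- c(v, sprintf("%s: last interval must be unbounded (missing interval [%s, Inf))",
                      table_name, cutoffs$upper[nrow(cutoffs)]))
  }
  if (nrow(cutoffs) > 1) {
    gaps <- cutoffs$lower[-1] != cutoffs$upper[-nrow(cutoffs)]
    if (any(gaps)) {
      v <- c(v, sprintf("%s: intervals do not partition [0, Inf) (gap or overlap after upper = %s)",
                        table_name,
                        paste(cutoffs$upper[-nrow(cutoffs)][gaps], collapse = ", ")))
    }
  }
  v
}

# Label for a score under a half-open [lower, upper) interval map.
cutoff_label <- function(score, cutoffs) {
  hit <- cutoffs$lower <= score & score < cutoffs$upper
  if (!any(hit)) return(NA_character_)
  cutoffs$label[which(hit)[1]]
}

#' Write a reference bundle back to its file formats
#'
#' Inverse of [load_reference_bundle()]: serializes the bundle's tables to
#' `allele_definitions.tsv`, `inhibitors.tsv`, `panel_drugs.tsv`,
#' `cutoffs.json` and `drug_classes.tsv` under `dir`, such that re-loading
#' yields an identical bundle.
#'
#' @param bundle A `pgx_reference` bundle.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_reference_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  join_set <- function(x) map_chr(x, paste, collapse = ";")

  bundle$alleles |>
    mutate(
      rsid_list = map_chr(.data$variants, function(vv) {
        if (length(vv) == 0) "" else paste(names(vv), vv, sep = "=", collapse = ";")
      }),
      activity_value = ifelse(is.na(.data$activity_value), "NA",
                              as.character(.data$activity_value))
    ) |>
    select("gene", "star_allele", "rsid_list", "activity_value",
           "function_class") |>
    readr::write_tsv(file.path(dir, "allele_definitions.tsv"))

  readr::write_tsv(bundle$inhibitors, file.path(dir, "inhibitors.tsv"))

  bundle$panel_rules |>
    mutate(
      actionable_phenotypes = join_set(.data$actionable_phenotypes),
      future_watch_phenotypes = join_set(.data$future_watch_phenotypes),
      eligible_routes = join_set(.data$eligible_routes),
      synonyms = join_set(.data$synonyms)
    ) |>
    readr::write_tsv(file.path(dir, "panel_drugs.tsv"))

  cut_out <- bundle$cyp2d6_cutoffs
  cut_out$upper[is.infinite(cut_out$upper)] <- NA_real_
  jsonlite::write_json(cut_out, file.path(dir, "cutoffs.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")

  readr::write_tsv(bundle$drug_classes, file.path(dir, "drug_classes.tsv"))
  invisible(dir)
}

# Resolve a free-text medication name to a lowercase generic panel/inhibitor
# name, applying the brand-name synonym map.
normalize_drug <- function(drug, bundle) {
  d <- tolower(str_trim(drug))
  unname(ifelse(d %in% names(bundle$synonym_map), bundle$synonym_map[d], d))
}
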