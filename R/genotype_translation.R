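#' Construct an rsID-level genotype call set for one sample
#'
#' @param sample_id Sample identifier.
#' @param calls Named list, one entry per assayed rsID, each an unordered pair
#'   of observed alleles (character vector of length 2). The token
#'   `"missing"` (or `NA`) marks a failed assay at that site.
#' @param cyp2d6_cnv CYP2D6 copy-number flag: `"yes"`, `"no"` or `"unknown"`.
#'   The assay detects the presence of a copy-number variation but not which
#'   allele is duplicated/deleted nor how many copies are present, so a
#'   positive flag makes the CYP2D6 activity score indeterminate.
#'
#' @return A `pgx_snp_calls` object.
#' @export
snp_call_set <- function(sample_id, calls = list(), cyp2d6_cnv = "no") {
  if (!cyp2d6_cnv %in% c("yes", "no", "unknown")) {
    abort("cyp2d6_cnv must be one of yes/no/unknown", class = "pgx_input_error")
  }
  calls <- map(calls, function(pair) {
    pair <- as.character(pair)
    if (length(pair) != 2) {
      abort("each genotype call must be a pair of alleles",
            class = "pgx_input_error")
    }
    pair
  })
  structure(list(sample_id = sample_id, calls = calls,
                 cyp2d6_cnv = cyp2d6_cnv),
            class = "pgx_snp_calls")
}

is_missing_call <- function(pair) {
  any(is.na(pair) | tolower(pair) == "missing")
}

gene_alleles <- function(gene, bundle) {
  al <- bundle$alleles |> filter(.data$gene == !!gene)
  if (nrow(al) == 0) {
    abort(sprintf("gene %s is not defined in the reference bundle", gene),
          class = "pgx_config_error")
  }
  al
}

# Multiset of variant observations at the gene's defining rsIDs, as a named
# count vector keyed "rsid=alt". Alleles not matching a defined alt are
# reference observations and contribute nothing.
observed_variant_counts <- function(snp_calls, al) {
  keys <- unlist(map2(
    map(al$variants, names), al$variants,
    function(rs, alt) paste(rs, alt, sep = "=")
  ))
  counts <- stats::setNames(integer(length(unique(keys))), unique(keys))
  for (key in names(counts)) {
    kv <- str_split(key, "=")[[1]]
    pair <- snp_calls$calls[[kv[1]]]
    if (!is.null(pair) && !is_missing_call(pair)) {
      counts[key] <- sum(pair == kv[2])
    }
  }
  counts
}

pair_variant_counts <- function(v1, v2, keys) {
  obs <- c(paste(names(v1), v1, sep = "="), paste(names(v2), v2, sep = "="))
  vapply(keys, function(k) sum(obs == k), integer(1))
}

indeterminate_diplotype <- function(gene, note) {
  tibble(gene = gene, allele_1 = NA_character_, allele_2 = NA_character_,
         diplotype = NA_character_, determinate = FALSE,
         ambiguity_note = note)
}

#' Infer a star-allele diplotype from rsID genotype calls
#'
#' Searches all unordered pairs of the gene's defined alleles for the pair
#' whose combined defining-variant multiset exactly explains every variant
#' allele observed at the gene's defining rsIDs. Sites absent from the call
#' set are taken as homozygous reference (the assay's default-to-reference
#' behaviour); a site explicitly recorded as `missing` makes the call
#' indeterminate, as do observations no allele pair can explain.
#'
#' When several pairs explain the observations equally, the pair with fewer
#' variant-defined alleles wins, then the lexicographically smallest star
#' numbers; alternatives are recorded in `ambiguity_note`.
#'
#' @param snp_calls A `pgx_snp_calls` object (see [snp_call_set()]).
#' @param gene Panel gene symbol.
#' @param bundle Reference bundle.
#' @return One-row tibble: `gene`, `allele_1`, `allele_2` (sorted, lowest star
#'   number first), `diplotype` ("a1/a2"), `determinate`, `ambiguity_note`.
#' @export
#'
#' @examples
#' bundle <- load_reference_bundle()
#' s <- snp_call_set("p1", list(rs4244285 = c("G", "A")))
#' infer_diplotype(s, "CYP2C19", bundle)  # *1/*2
infer_diplotype <- function(snp_calls, gene, bundle) {
  al <- gene_alleles(gene, bundle)
  rsids <- unique(unlist(map(al$variants, names)))

  miss <- rsids[map_lgl(rsids, function(rs) {
    pair <- snp_calls$calls[[rs]]
    !is.null(pair) && is_missing_call(pair)
  })]
  if (length(miss) > 0) {
    return(indeterminate_diplotype(
      gene, sprintf("missing genotype call at defining site(s): %s",
                    paste(miss, collapse = ", "))
    ))
  }

  obs <- observed_variant_counts(snp_calls, al)
  keys <- names(obs)

  ref_allele <- al$star_allele[lengths(al$variants) == 0][1]
  n <- nrow(al)
  idx <- which(upper.tri(matrix(TRUE, n, n), diag = TRUE), arr.ind = TRUE)
  match_rows <- purrr::map_dfr(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    pc <- pair_variant_counts(al$variants[[i]], al$variants[[j]], keys)
    if (!all(pc == obs)) return(NULL)
    alleles <- sort_alleles(al$star_allele[i], al$star_allele[j],
                            ref = ref_allele)
    tibble(allele_1 = alleles[1], allele_2 = alleles[2],
           n_variant_alleles = sum(lengths(al$variants[c(i, j)]) > 0))
  })

  if (nrow(match_rows) == 0) {
    return(indeterminate_diplotype(
      gene, "observed variants are not explained by any defined allele pair"
    ))
  }

  ord <- order(match_rows$n_variant_alleles,
               allele_sort_key(match_rows$allele_1),
               match_rows$allele_1,
               allele_sort_key(match_rows$allele_2),
               match_rows$allele_2)
  match_rows <- match_rows[ord, , drop = FALSE]
  best <- match_rows[1, ]
  note <- ""
  if (nrow(match_rows) > 1) {
    alts <- paste(match_rows$allele_1[-1], match_rows$allele_2[-1], sep = "/")
    note <- sprintf("equally consistent alternative(s): %s",
                    paste(alts, collapse = ", "))
  }
  tibble(gene = gene, allele_1 = best$allele_1, allele_2 = best$allele_2,
         diplotype = paste(best$allele_1, best$allele_2, sep = "/"),
         determinate = TRUE, ambiguity_note = note)
}

#' Activity score of a diplotype
#'
#' Sum of the two alleles' activity values. Defined for CYP2D6 and CYP2C9
#' only. A detected CYP2D6 copy-number variation makes the score
#' indeterminate because the assay cannot resolve which allele is affected
#' nor the copy count; an indeterminate diplotype propagates.
#'
#' @param diplotype One-row diplotype tibble from [infer_diplotype()].
#' @param cnv_flag CYP2D6 copy-number flag (`"yes"`, `"no"`, `"unknown"`).
#' @param bundle Reference bundle.
#' @return Numeric score, or the string `"indeterminate"`.
#' @export
activity_score <- function(diplotype, cnv_flag = "no", bundle) {
  gene <- diplotype$gene
  if (!gene %in% c("CYP2D6", "CYP2C9")) {
    abort(sprintf("activity scores are defined for CYP2D6 and CYP2C9, not %s",
                  gene),
          class = "pgx_input_error")
  }
  if (gene == "CYP2D6" && identical(cnv_flag, "yes")) return("indeterminate")
  if (!isTRUE(diplotype$determinate)) return("indeterminate")
  al <- gene_alleles(gene, bundle)
  vals <- al$activity_value[match(c(diplotype$allele_1, diplotype$allele_2),
                                  al$star_allele)]
  if (any(is.na(vals))) {
    abort(sprintf("allele of %s lacks an activity value", gene),
          class = "pgx_config_error")
  }
  sum(vals)
}

#' Translate a diplotype to a genotype-based phenotype
#'
#' CYP2D6 and CYP2C9 are labelled through their activity score and the
#' bundle's cutoff maps (legacy CYP2D6 scheme: a score of 1.0 is a normal
#' metabolizer). CYP2C19, CYP3A5 and SLCO1B1 use the bundle's diplotype
#' lookup. VKORC1, CYP4F2 and the CYP2C cluster are reported as genotype
#' strings rather than metabolizer labels. Indeterminate inputs propagate to
#' an `indeterminate` label; a determinate diplotype absent from the lookup
#' is labelled `indeterminate` with an explanatory note, not an error.
#'
#' @inheritParams activity_score
#' @return One-row tibble: `gene`, `diplotype`, `determinate`,
#'   `activity_score` (numeric, `NA` where not applicable or indeterminate),
#'   `genotype_based_phenotype`, `ambiguity_note`.
#' @export
#'
#' @examples
#' bundle <- load_reference_bundle()
#' d <- tibble::tibble(gene = "CYP2C19", allele_1 = "*1", allele_2 = "*17",
#'                     diplotype = "*1/*17", determinate = TRUE,
#'                     ambiguity_note = "")
#' assign_phenotype(d, bundle = bundle)$genotype_based_phenotype  # "RM"
assign_phenotype <- function(diplotype, cnv_flag = "no", bundle) {
  gene <- diplotype$gene
  if (!gene %in% PANEL_GENES) {
    abort(sprintf("gene %s is not on the 8-gene panel", gene),
          class = "pgx_input_error")
  }
  dip_string <- diplotype$diplotype
  dip_determinate <- diplotype$determinate
  dip_note <- diplotype$ambiguity_note %||% ""
  out <- tibble(
    gene = gene,
    diplotype = dip_string,
    determinate = dip_determinate,
    activity_score = NA_real_,
    genotype_based_phenotype = "indeterminate",
    ambiguity_note = dip_note
  )
  if (gene == "CYP2D6" && identical(cnv_flag, "yes")) {
    out$genotype_based_phenotype <- "indeterminate"
    out$ambiguity_note <- paste0(
      "copy-number variation detected; allele copy count unresolvable. ",
      out$ambiguity_note
    )
    return(out)
  }
  if (!isTRUE(diplotype$determinate)) return(out)

  if (gene %in% c("CYP2D6", "CYP2C9")) {
    score <- activity_score(diplotype, cnv_flag, bundle)
    cutoffs <- if (gene == "CYP2D6") bundle$cyp2d6_cutoffs else bundle$cyp2c9_cutoffs
    out$activity_score <- score
    out$genotype_based_phenotype <- cutoff_label(score, cutoffs)
  } else if (gene %in% GENOTYPE_REPORT_GENES) {
    out$genotype_based_phenotype <- diplotype$diplotype
  } else {
    hit <- bundle$phenotype_lookup |>
      filter(.data$gene == !!gene, .data$diplotype == !!diplotype$diplotype)
    if (nrow(hit) == 1) {
      out$genotype_based_phenotype <- hit$phenotype
    } else {
      out$genotype_based_phenotype <- "indeterminate"
      out$ambiguity_note <- sprintf("diplotype %s has no phenotype lookup entry",
                                    diplotype$diplotype)
    }
  }
  out
}

#' Phenotype calls for all eight panel genes of one sample
#'
#' Runs [infer_diplotype()] and [assign_phenotype()] for every panel gene.
#'
#' @param snp_calls A `pgx_snp_calls` object.
#' @param bundle Reference bundle.
#' @return Tibble with one row per panel gene, plus a `sample_id` column.
#' @export
call_phenotypes <- function(snp_calls, bundle) {
  purrr::map_dfr(PANEL_GENES, function(g) {
    d <- infer_diplotype(snp_calls, g, bundle)
    assign_phenotype(d, cnv_flag = snp_calls$cyp2d6_cnv, bundle = bundle)
  }) |>
    mutate(sample_id = snp_calls$sample_id, .before = 1)
}
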