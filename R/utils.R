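# Internal helpers shared across modules.

#' @importFrom rlang abort %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_dbl map_lgl map2 map2_chr map2_lgl
#' @importFrom stringr str_split str_trim str_detect
NULL

# The eight genes of the assay panel.
PANEL_GENES <- c(
  "CYP2C19", "CYP2D6", "CYP2C9", "CYP3A5",
  "SLCO1B1", "CYP4F2", "VKORC1", "CYP2C-cluster"
)

# Genes whose phenotype is a genotype string, not a metabolizer label.
GENOTYPE_REPORT_GENES <- c("VKORC1", "CYP4F2", "CYP2C-cluster")

# Metabolizer label rank, low activity first. Used for phenoconversion
# monotonicity; genotype-string labels have no rank (NA).
PHENOTYPE_RANK <- c(
  "PM" = 1, "poor function" = 1,
  "IM" = 2, "decreased function" = 2,
  "NM" = 3, "normal function" = 3,
  "RM" = 4, "increased function" = 4,
  "UM" = 5
)

phenotype_rank <- function(label) {
  unname(PHENOTYPE_RANK[label])
}

# round() in R rounds half to even; printed clinical percentages use
# arithmetic half-up rounding (0.5 always rounds away from zero).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(abs(x) * scale + 0.5) / scale * sign(x)
}

# Percent formatting convention for cohort tables: whole percent, except one
# decimal for fractions below 5%.
format_percent <- function(count, total) {
  if (total == 0) return(numeric(0))
  pct <- 100 * count / total
  ifelse(pct < 5, round_half_up(pct, 1), round_half_up(pct, 0))
}

# Sort key for star alleles: numeric star number when present ("*41" -> 41),
# otherwise alphabetical (single-SNP loci use genotype letters).
allele_sort_key <- function(allele) {
  num <- suppressWarnings(as.numeric(sub("^\\*", "", allele)))
  ifelse(is.na(num), NA_real_, num)
}

# Star alleles sort by star number; single-letter genotypes put the
# reference allele first (conventional ref/alt presentation) when known.
sort_alleles <- function(a, b, ref = NULL) {
  ka <- allele_sort_key(a)
  kb <- allele_sort_key(b)
  if (is.na(ka) && is.na(kb) && !is.null(ref)) {
    if (identical(b, ref) && !identical(a, ref)) return(c(b, a))
    return(c(a, b))
  }
  swap <- if (!is.na(ka) && !is.na(kb)) ka > kb else a > b
  if (isTRUE(swap)) c(b, a) else c(a, b)
}

assert_file_exists <- function(path, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: %s", what, path), class = "pgx_io_error")
  }
  invisible(path)
}
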