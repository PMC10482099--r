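test_that("diplotypes resolve from rsID calls: reference default, het variants, missing sites", {
  # all defining sites homozygous reference -> *1/*1
  s_ref <- snp_call_set("ref", list(rs4244285 = c("G", "G"),
                                    rs4986893 = c("G", "G"),
                                    rs12248560 = c("C", "C")))
  d <- infer_diplotype(s_ref, "CYP2C19", bundle)
  expect_identical(d$diplotype, "*1/*1")
  expect_true(d$determinate)

  # sites absent from the call set default to reference as well
  d_empty <- infer_diplotype(snp_call_set("none"), "CYP2C19", bundle)
  expect_identical(d_empty$diplotype, "*1/*1")

  # heterozygous at the single site defining CYP2C19*2 -> *1/*2
  s_het <- snp_call_set("het", list(rs4244285 = c("G", "A")))
  expect_identical(infer_diplotype(s_het, "CYP2C19", bundle)$diplotype,
                   "*1/*2")

  # compound het at two different allele-defining sites -> trans assignment
  s_trans <- snp_call_set("trans", list(rs4244285 = c("G", "A"),
                                        rs12248560 = c("C", "T")))
  expect_identical(infer_diplotype(s_trans, "CYP2C19", bundle)$diplotype,
                   "*2/*17")

  # an explicit missing call at a defining site -> indeterminate
  s_miss <- snp_call_set("miss", list(rs4244285 = c("missing", "missing"),
                                      rs12248560 = c("C", "T")))
  d_miss <- infer_diplotype(s_miss, "CYP2C19", bundle)
  expect_false(d_miss$determinate)
  expect_match(d_miss$ambiguity_note, "missing")

  expect_error(infer_diplotype(s_ref, "HLA-B", bundle),
               class = "pgx_config_error")
})

test_that("activity scores sum allele values and CNV makes CYP2D6 indeterminate", {
  expect_identical(activity_score(make_diplotype("CYP2D6", "*1", "*1"),
                                  "no", bundle), 2)
  expect_identical(activity_score(make_diplotype("CYP2D6", "*1", "*4"),
                                  "no", bundle), 1)
  expect_identical(activity_score(make_diplotype("CYP2D6", "*4", "*41"),
                                  "no", bundle), 0.5)
  expect_identical(activity_score(make_diplotype("CYP2D6", "*1", "*1"),
                                  "yes", bundle), "indeterminate")
  expect_identical(activity_score(make_diplotype("CYP2C9", "*1", "*2"),
                                  "no", bundle), 1.5)
  expect_error(activity_score(make_diplotype("CYP2C19", "*1", "*1"),
                              "no", bundle),
               class = "pgx_input_error")
})

test_that("phenotype assignment follows score cutoffs, diplotype lookups and genotype-string reporting", {
  lbl <- function(gene, a1, a2, cnv = "no") {
    assign_phenotype(make_diplotype(gene, a1, a2), cnv,
                     bundle)$genotype_based_phenotype
  }
  expect_identical(lbl("CYP2D6", "*1", "*4"), "NM")   # score 1.0 is NM (legacy)
  expect_identical(lbl("CYP2D6", "*4", "*4"), "PM")   # zero activity
  expect_identical(lbl("CYP2D6", "*4", "*41"), "IM")
  expect_identical(lbl("CYP2D6", "*1", "*1", cnv = "yes"), "indeterminate")
  expect_identical(lbl("CYP2C19", "*1", "*17"), "RM")
  expect_identical(lbl("CYP2C19", "*2", "*2"), "PM")
  expect_identical(lbl("CYP3A5", "*3", "*3"), "PM")
  expect_identical(lbl("CYP3A5", "*1", "*3"), "NM")   # expresser
  expect_identical(lbl("SLCO1B1", "*1", "*5"), "decreased function")
  expect_identical(lbl("CYP2C9", "*1", "*3"), "IM")
  expect_identical(lbl("VKORC1", "G", "A"), "G/A")
  expect_identical(lbl("CYP4F2", "*1", "*3"), "*1/*3")
  # indeterminate diplotype propagates without raising
  indet <- tibble::tibble(gene = "CYP2C19", allele_1 = NA, allele_2 = NA,
                          diplotype = NA_character_, determinate = FALSE,
                          ambiguity_note = "x")
  expect_identical(assign_phenotype(indet, "no",
                                    bundle)$genotype_based_phenotype,
                   "indeterminate")
})

test_that("phenotype label rank is non-decreasing in CYP2D6 activity score", {
  rank_of <- c(PM = 1, IM = 2, NM = 3, UM = 4)
  scores <- seq(0, 4, by = 0.25)
  labels <- vapply(scores, pgxpanel:::cutoff_label,
                   character(1), cutoffs = bundle$cyp2d6_cutoffs)
  expect_true(all(diff(rank_of[labels]) >= 0))
})

test_that("matcher agrees with the brute-force pair-enumeration oracle on random call sets", {
  set.seed(42)
  genes <- unique(bundle$alleles$gene)
  n_cases <- 1000
  for (k in seq_len(n_cases)) {
    gene <- genes[(k - 1) %% length(genes) + 1]
    calls <- random_gene_calls(gene, bundle)
    got <- infer_diplotype(snp_call_set("x", calls), gene, bundle)
    has_missing <- any(vapply(calls, function(p) any(p == "missing"),
                              logical(1)))
    hits <- oracle_diplotypes(calls, gene, bundle)
    if (has_missing) {
      expect_false(got$determinate)
    } else if (length(hits) == 0) {
      expect_false(got$determinate)
    } else {
      expect_true(got$determinate)
      expect_true(paste(sort(c(got$allele_1, got$allele_2)),
                        collapse = "|") %in% hits)
    }
  }
})

test_that("every determinate diplotype of shipped alleles gets a non-indeterminate label", {
  for (g in unique(bundle$alleles$gene)) {
    al <- bundle$alleles$star_allele[bundle$alleles$gene == g]
    for (i in seq_along(al)) {
      for (j in i:length(al)) {
        pair <- pgxpanel:::sort_alleles(al[i], al[j])
        ph <- assign_phenotype(make_diplotype(g, pair[1], pair[2]),
                               "no", bundle)
        expect_false(identical(ph$genotype_based_phenotype, "indeterminate"),
                     info = paste(g, pair[1], pair[2]))
      }
    }
  }
})

test_that("identical inputs yield identical calls (determinism)", {
  s <- snp_call_set("d", list(rs3892097 = c("G", "A"),
                              rs28371725 = c("C", "T")))
  first <- call_phenotypes(s, bundle)
  expect_identical(call_phenotypes(s, bundle), first)
})
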