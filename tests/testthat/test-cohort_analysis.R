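fixture_results <- local({
  cohort <- fixture_cohort_table3(bundle)
  interpret_cohort(cohort, bundle)
})
fixture_phenotypes <- purrr::map_dfr(fixture_results, "phenotypes")

test_that("frequency tables count every label, sum to cohort size and recompute percents", {
  for (g in unique(fixture_phenotypes$gene)) {
    tab <- phenotype_frequency_table(
      dplyr::filter(fixture_phenotypes, gene == g), g
    )
    expect_identical(sum(tab$count), 61L)
    expect_identical(unique(tab$n_total), 61L)
    # percent recomputes from its count under the table's precision rule
    for (i in seq_len(nrow(tab))) {
      raw <- 100 * tab$count[i] / 61
      digits <- if (raw < 5) 1 else 0
      expect_identical(tab$percent[i],
                       floor(raw * 10^digits + 0.5) / 10^digits)
    }
  }
  empty <- phenotype_frequency_table(fixture_phenotypes[0, ], "CYP2C19")
  expect_identical(nrow(empty), 0L)
  expect_error(phenotype_frequency_table(fixture_phenotypes, "CYP2C19"),
               class = "pgx_input_error")
})

test_that("fixture cohort reproduces the published genotype-based marginals", {
  tab <- function(g) {
    t <- phenotype_frequency_table(dplyr::filter(fixture_phenotypes, gene == g), g)
    stats::setNames(t$count, t$label)
  }
  expect_equal(tab("CYP2C19"),
               c(PM = 2L, IM = 12L, NM = 30L, RM = 16L, UM = 1L),
               ignore_attr = FALSE)
  expect_equal(tab("CYP2D6"),
               c(PM = 1L, IM = 7L, NM = 52L, indeterminate = 1L))
  expect_equal(unname(tab("CYP3A5")[c("NM", "PM")]), c(11L, 50L))
  expect_equal(unname(tab("SLCO1B1")[c("decreased function",
                                       "normal function")]),
               c(15L, 46L))
  expect_equal(unname(tab("CYP2C9")[c("IM", "NM")]), c(25L, 36L))
  expect_equal(unname(tab("VKORC1")[c("G/G", "G/A", "A/A")]),
               c(22L, 27L, 12L))
  expect_equal(unname(tab("CYP4F2")[c("*1/*1", "*1/*3", "*3/*3")]),
               c(27L, 27L, 7L))
  expect_equal(unname(tab("CYP2C-cluster")[c("G/G", "G/A", "A/A")]),
               c(46L, 13L, 2L))
})

test_that("phenoconversion summary: 13 of 14 exposed convert and PM prevalence reaches 20%", {
  cyp2d6 <- dplyr::filter(fixture_phenotypes, gene == "CYP2D6")
  s <- phenoconversion_summary(cyp2d6)
  expect_identical(s$n, 61L)
  expect_identical(s$n_exposed, 14L)
  expect_identical(s$n_converted, 13L)
  expect_identical(s$pm_prevalence_after, 20)
  expect_lt(s$pm_prevalence_before, 5)

  # degenerate case: nobody exposed
  none <- cyp2d6 |>
    dplyr::mutate(inhibitor_strength_applied = "none",
                  clinical_phenotype = genotype_based_phenotype,
                  phenoconverted = FALSE)
  s0 <- phenoconversion_summary(none)
  expect_identical(s0$n_converted, 0L)
  expect_identical(s0$pm_prevalence_before, s0$pm_prevalence_after)

  # everyone on a strong inhibitor: all but the indeterminate become PM
  all_strong <- purrr::map_dfr(seq_len(nrow(cyp2d6)), function(i) {
    base <- cyp2d6[i, ]
    base$inhibitor_strength_applied <- NULL
    base$clinical_phenotype <- NULL
    base$phenoconverted <- NULL
    phenoconvert(base, "strong")
  })
  s_strong <- phenoconversion_summary(all_strong)
  clin <- stats::setNames(s_strong$clinical_counts$count,
                          s_strong$clinical_counts$label)
  expect_identical(unname(clin["PM"]), 60L)
  expect_identical(unname(clin["indeterminate"]), 1L)
})

test_that("actionability summary counts pairs once per patient and splits by class", {
  two_pairs <- tibble::tibble(
    sample_id = "p1",
    drug = c("omeprazole", "tramadol"),
    gene = c("CYP2C19", "CYP2D6"),
    clinical_phenotype = c("IM", "NM"),
    currently_actionable = c(TRUE, FALSE),
    future_watch = c(FALSE, FALSE),
    evidence_grade = c("moderate", "strong")
  )
  s <- actionability_summary(two_pairs, bundle)
  expect_identical(s$n_pairs, 2L)
  expect_identical(s$n_actionable_pairs, 1L)
  expect_identical(s$n_actionable_moderate_plus, 1L)
  expect_setequal(s$by_class$class, c("PPI", "opioid"))

  # two PPIs in one CYP2C19 IM patient are two actionable pairs
  two_ppi <- two_pairs |>
    dplyr::mutate(drug = c("omeprazole", "pantoprazole"),
                  gene = "CYP2C19", clinical_phenotype = "IM",
                  currently_actionable = TRUE)
  expect_identical(actionability_summary(two_ppi, bundle)$n_actionable_pairs,
                   2L)

  # a duplicated pair within a patient is not double counted
  dup <- dplyr::bind_rows(two_pairs, two_pairs[1, ])
  expect_identical(actionability_summary(dup, bundle)$n_pairs, 2L)

  empty <- actionability_summary(list(), bundle)
  expect_identical(empty$n_pairs, 0L)
  expect_identical(empty$n_actionable_pairs, 0L)

  # cohort-level count equals the sum of per-patient classifications
  per_patient <- purrr::map(fixture_results, "actionability")
  s_cohort <- actionability_summary(per_patient, bundle)
  expect_identical(
    s_cohort$n_actionable_pairs,
    sum(purrr::map_int(per_patient, ~ sum(.x$currently_actionable)))
  )
})

test_that("demographics summary uses the sample SD convention", {
  trio <- tibble::tibble(age = c(40, 50, 60), sex = "Female",
                         race = "White", ethnicity = "Not Hispanic or Latino")
  s <- demographics_summary(trio)
  expect_identical(s$age$mean, 50)
  expect_identical(s$age$sd, 10)
  single <- demographics_summary(trio[2, ])
  expect_identical(single$sex$percent, 100)
  expect_error(demographics_summary(trio[0, ]), class = "pgx_input_error")

  fixture_demo <- purrr::map_dfr(fixture_cohort_table3(bundle),
                                 "demographics")
  sf <- demographics_summary(fixture_demo)
  expect_identical(sf$n, 61L)
  expect_identical(sf$age$min, 25)
  expect_identical(sf$age$max, 71)
  expect_identical(
    stats::setNames(sf$sex$count, sf$sex$label)[c("Female", "Male")],
    c(Female = 39L, Male = 22L)
  )
})

test_that("funnel summary reproduces stage rates and rejects non-monotone records", {
  f <- funnel_summary(fixture_funnel_fig2())
  expect_identical(f$counts$identified, 244L)
  expect_identical(f$counts$contacted, 162L)
  expect_identical(f$counts$confirmed_eligible, 145L)
  expect_identical(f$counts$agreed, 110L)
  expect_identical(f$counts$kit_returned, 61L)
  expect_identical(f$rates$contact, 66)
  expect_identical(f$rates$consent, 76)
  expect_identical(f$rates$kit_return, 55)
  # stage counts are non-increasing along the funnel
  expect_true(all(diff(unlist(f$counts[c("identified", "contacted",
                                         "confirmed_eligible", "agreed",
                                         "kit_returned")])) <= 0))
  channels <- stats::setNames(f$channels$count, f$channels$channel)
  expect_identical(unname(channels[c("initial call", "follow-up call",
                                     "portal message", "in person")]),
                   c(50L, 10L, 47L, 3L))
  exclusions <- stats::setNames(f$exclusions$count, f$exclusions$reason)
  expect_identical(unname(exclusions[c("no panel drug", "not plan-enrolled",
                                       "prior PGx test")]),
                   c(10L, 6L, 1L))

  all_true <- fixture_funnel_fig2()[1:5, ] |>
    dplyr::mutate(contacted = TRUE, confirmed_eligible = TRUE, agreed = TRUE,
                  consent_channel = "initial call", kit_returned = TRUE,
                  exclusion_reason = NA_character_, turnaround_days = 30)
  f_all <- funnel_summary(all_true)
  expect_identical(unlist(f_all$rates), c(contact = 100, consent = 100,
                                          kit_return = 100))

  broken <- fixture_funnel_fig2()
  broken$agreed[200] <- TRUE  # agreed without being contacted
  expect_error(funnel_summary(broken), "F200", class = "pgx_input_error")
})

test_that("survey summary rounds responder fractions half-up to whole percents", {
  s <- survey_summary(fixture_survey_fig5())
  expect_identical(s$n_responders, 24L)
  expect_identical(s$pct_prefers_specialist, 71)  # 17/24
  expect_identical(s$pct_perceived_impact, 25)    # 6/24
  expect_gt(s$pct_overall_positive, 80)
  s0 <- survey_summary(fixture_survey_fig5()[0, ])
  expect_identical(s0$n_responders, 0L)
  expect_true(is.na(s0$pct_prefers_specialist))
})
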