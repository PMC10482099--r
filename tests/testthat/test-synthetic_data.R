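test_that("fixture cohort is deterministic and matches its printed structure", {
  cohort <- fixture_cohort_table3(bundle)
  expect_length(cohort, 61)
  again <- fixture_cohort_table3(bundle)
  expect_identical(purrr::map(cohort, function(p) p$snp_calls$calls),
                   purrr::map(again, function(p) p$snp_calls$calls))
  expect_identical(purrr::map(cohort, "medications"),
                   purrr::map(again, "medications"))

  # patient 61 carries the CNV flag; everyone else does not
  expect_identical(cohort[[61]]$snp_calls$cyp2d6_cnv, "yes")
  expect_true(all(purrr::map_chr(cohort[1:60],
                                 ~ .x$snp_calls$cyp2d6_cnv) == "no"))

  # inhibitor exposure: 11 strong + 3 moderate
  strengths <- purrr::map_chr(cohort,
                              ~ inhibitor_strength(.x$medications, bundle))
  expect_identical(sum(strengths == "strong"), 11L)
  expect_identical(sum(strengths == "moderate"), 3L)
  expect_identical(which(strengths == "strong"), 9:19)
  expect_identical(which(strengths == "moderate"), c(1L, 20L, 21L))

  # patients 59-61 have only topical tacrolimus: zero active panel drugs
  for (i in 59:61) {
    expect_identical(nrow(active_panel_drugs(cohort[[i]]$medications,
                                             bundle)), 0L)
  }
  # every other patient carries at least one active panel drug
  for (i in 1:58) {
    expect_gt(nrow(active_panel_drugs(cohort[[i]]$medications, bundle)), 0)
  }
})

test_that("funnel and survey fixtures are deterministic and monotone", {
  f1 <- fixture_funnel_fig2()
  expect_identical(f1, fixture_funnel_fig2())
  expect_identical(nrow(f1), 244L)
  expect_no_error(funnel_summary(f1))
  expect_identical(fixture_survey_fig5(), fixture_survey_fig5())
})

test_that("simulated cohorts are seed-reproducible and respect n = 0", {
  expect_identical(simulate_cohort(cohort_params(n = 0), bundle), list())
  p <- cohort_params(n = 25, seed = 7L)
  c1 <- simulate_cohort(p, bundle)
  c2 <- simulate_cohort(p, bundle)
  expect_identical(purrr::map(c1, function(x) x$snp_calls$calls),
                   purrr::map(c2, function(x) x$snp_calls$calls))
  expect_identical(purrr::map(c1, "medications"),
                   purrr::map(c2, "medications"))
  expect_identical(purrr::map(c1, "demographics"),
                   purrr::map(c2, "demographics"))
  c3 <- simulate_cohort(cohort_params(n = 25, seed = 8L), bundle)
  expect_false(identical(purrr::map(c1, function(x) x$snp_calls$calls),
                         purrr::map(c3, function(x) x$snp_calls$calls)))

  expect_error(cohort_params(inhibitor_exposure_rate = 1.2),
               class = "pgx_input_error")
  expect_error(cohort_params(allele_freqs = list(CYP3A5 = c(`*1` = 0.5,
                                                            `*3` = 0.4))),
               class = "pgx_input_error")
})

test_that("Hardy-Weinberg sampling recovers diplotype frequencies at n = 2000", {
  freqs <- default_allele_freqs()
  freqs$CYP3A5 <- c(`*1` = 0.1, `*3` = 0.9)
  p <- cohort_params(n = 2000, allele_freqs = freqs, seed = 11L)
  cohort <- simulate_cohort(p, bundle)
  # CYP3A5 *3/*3 is homozygous variant at rs776746
  hom33 <- sum(purrr::map_lgl(cohort, function(pt) {
    all(pt$snp_calls$calls[["rs776746"]] == "G")
  }))
  expected <- 0.9^2
  band <- stats::qbinom(c(0.005, 0.995), 2000, expected)
  expect_gte(hom33, band[1])
  expect_lte(hom33, band[2])

  # heterozygote frequency too (2pq)
  het <- sum(purrr::map_lgl(cohort, function(pt) {
    length(unique(pt$snp_calls$calls[["rs776746"]])) == 2
  }))
  band_het <- stats::qbinom(c(0.005, 0.995), 2000, 2 * 0.1 * 0.9)
  expect_gte(het, band_het[1])
  expect_lte(het, band_het[2])
})

test_that("age distribution recovers its generating mean on a large cohort", {
  cohort <- simulate_cohort(cohort_params(n = 500, age_mean = 51,
                                          age_sd = 10, seed = 3L), bundle)
  ages <- purrr::map_dbl(cohort, ~ .x$demographics$age)
  expect_lt(abs(mean(ages) - 51), 1)
})

test_that("funnel completion matches the product of stage rates at n = 10000", {
  p <- funnel_params(n_identified = 10000, seed = 5L)
  records <- simulate_funnel(p)
  expect_no_error(funnel_summary(records))
  completion <- mean(records$kit_returned)
  p_complete <- p$p_contact * p$p_confirm_eligible * p$p_agree * p$p_return
  se <- sqrt(p_complete * (1 - p_complete) / 10000)
  expect_lt(abs(completion - p_complete), 3 * se)
  # turnaround strictly positive (truncated at zero)
  expect_true(all(records$turnaround_days[records$kit_returned] > 0))
  # seed reproducibility
  expect_identical(records, simulate_funnel(p))

  expect_error(funnel_params(p_contact = -0.1), class = "pgx_input_error")
})

test_that("simulation leaves the global RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_cohort(cohort_params(n = 3, seed = 99L), bundle))
  invisible(simulate_funnel(funnel_params(n_identified = 10, seed = 99L)))
  expect_identical(.Random.seed, before)
})

test_that("cohort files round-trip through write and read", {
  tmp <- withr::local_tempdir()
  cohort <- fixture_cohort_table3(bundle)[1:5]
  write_cohort_files(cohort, tmp)
  back <- read_cohort_files(tmp)
  expect_length(back, 5)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$sample_id, cohort[[i]]$sample_id)
    expect_identical(back[[i]]$snp_calls$calls, cohort[[i]]$snp_calls$calls)
    expect_identical(back[[i]]$snp_calls$cyp2d6_cnv,
                     cohort[[i]]$snp_calls$cyp2d6_cnv)
    expect_identical(back[[i]]$medications, cohort[[i]]$medications)
  }
})
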