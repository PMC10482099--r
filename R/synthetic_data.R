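# Reference (wildtype) observation token at each assayed site, used when
# synthesizing rsID-level genotype calls from a chosen diplotype.
REF_BASES <- c(
  rs4244285 = "G", rs4986893 = "G", rs12248560 = "C",
  rs16947 = "G", rs35742686 = "T", rs3892097 = "G", rs5030655 = "T",
  rs1065852 = "C", rs28371706 = "C", rs28371725 = "C",
  rs1799853 = "C", rs1057910 = "A",
  rs776746 = "A", rs10264272 = "C", rs41303343 = "-",
  rs4149056 = "T", rs2108622 = "C", rs9923231 = "G", rs12777823 = "G"
)

# Evaluate `code` under a locally seeded RNG, restoring global RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# rsID calls implied by a diplotype: alt copies contributed by each allele,
# padded with the reference base.
diplotype_to_calls <- function(gene, allele_1, allele_2, bundle) {
  al <- gene_alleles(gene, bundle)
  variants <- c(al$variants[[match(allele_1, al$star_allele)]],
                al$variants[[match(allele_2, al$star_allele)]])
  rsids <- unique(unlist(map(al$variants, names)))
  calls <- map(rsids, function(rs) {
    alts <- unname(variants[names(variants) == rs])
    ref <- REF_BASES[[rs]] %||% "ref"
    c(alts, rep(ref, 2 - length(alts)))
  })
  stats::setNames(calls, rsids)
}

make_patient <- function(sample_id, diplotypes, cnv, medications, demo_row) {
  calls <- list()
  for (i in seq_len(nrow(diplotypes))) {
    calls <- c(calls, diplotype_to_calls(diplotypes$gene[i],
                                         diplotypes$allele_1[i],
                                         diplotypes$allele_2[i],
                                         attr(diplotypes, "bundle")))
  }
  structure(
    list(sample_id = sample_id,
         snp_calls = snp_call_set(sample_id, calls, cyp2d6_cnv = cnv),
         medications = medications,
         demographics = dplyr::bind_cols(tibble(sample_id = sample_id),
                                         demo_row)),
    class = "pgx_patient"
  )
}

block_labels <- function(breaks, values, n) {
  out <- character(n)
  start <- 1
  for (k in seq_along(breaks)) {
    if (breaks[k] >= start) out[start:breaks[k]] <- values[k]
    start <- breaks[k] + 1
  }
  out
}

#' Deterministic 61-patient fixture cohort
#'
#' Reconstructs a cohort whose per-gene phenotype marginals match the pilot's
#' published frequency table, realized as representative diplotypes assigned
#' in contiguous patient-index blocks (the joint structure across genes is
#' unpublished; block assignment anchored at patient 1 is the auditable
#' choice). Patient 61 carries a CYP2D6 copy-number flag and is therefore
#' indeterminate for that gene. CYP2D6 inhibitor exposure follows the pilot's
#' pattern: a strong inhibitor (fluoxetine) for patients 9-19 (all
#' genotype-based normal metabolizers), a moderate inhibitor (duloxetine) for
#' patients 20-21 (normal metabolizers) and patient 1 (the genotype-based
#' poor metabolizer, the one exposed patient who cannot convert further).
#' Every patient 1-58 carries one active oral panel drug; patients 59-61
#' carry only topical tacrolimus (no systemic exposure, hence zero active
#' panel drugs).
#'
#' @param bundle Reference bundle.
#' @return List of 61 `pgx_patient` records.
#' @export
#'
#' @examples
#' cohort <- fixture_cohort_table3()
#' length(cohort)  # 61
fixture_cohort_table3 <- function(bundle = load_reference_bundle()) {
  n <- 61
  gene_blocks <- list(
    CYP2C19 = list(breaks = c(2, 14, 44, 60, 61),
                   dips = c("*2/*2", "*1/*2", "*1/*1", "*1/*17", "*17/*17")),
    CYP2D6 = list(breaks = c(1, 8, 61),
                  dips = c("*4/*4", "*4/*41", "*1/*1")),
    CYP2C9 = list(breaks = c(25, 61), dips = c("*1/*2", "*1/*1")),
    CYP3A5 = list(breaks = c(11, 61), dips = c("*1/*3", "*3/*3")),
    SLCO1B1 = list(breaks = c(15, 61), dips = c("*1/*5", "*1/*1")),
    CYP4F2 = list(breaks = c(27, 54, 61),
                  dips = c("*1/*1", "*1/*3", "*3/*3")),
    VKORC1 = list(breaks = c(22, 49, 61), dips = c("G/G", "G/A", "A/A")),
    `CYP2C-cluster` = list(breaks = c(46, 59, 61),
                           dips = c("G/G", "G/A", "A/A"))
  )

  panel_drug <- block_labels(
    c(8, 9, 15, 23, 31, 39, 44, 50, 53, 55, 58, 61),
    c("omeprazole", "tramadol", "omeprazole", "tramadol", "escitalopram",
      "pantoprazole", "sertraline", "ibuprofen", "celecoxib", "meloxicam",
      "hydrocodone", "tacrolimus"),
    n
  )
  inhibitor <- rep(NA_character_, n)
  inhibitor[9:19] <- "fluoxetine"
  inhibitor[c(1, 20, 21)] <- "duloxetine"

  ages <- pmin(pmax(round(stats::qnorm(stats::ppoints(n), 50.93, 10.21)),
                    25), 71)
  ages[1] <- 25   # published age range: 25-71
  ages[n] <- 71
  sex <- block_labels(c(39, 61), c("Female", "Male"), n)
  race <- block_labels(c(53, 56, 59, 61),
                       c("White", "Asian", "Other",
                         "Black or African American"), n)
  ethnicity <- block_labels(c(59, 60, 61),
                            c("Not Hispanic or Latino", "Hispanic or Latino",
                              "Unknown/Not Reported"), n)

  map(seq_len(n), function(i) {
    dips <- purrr::imap_dfr(gene_blocks, function(spec, g) {
      dip <- block_labels(spec$breaks, spec$dips, n)[i]
      parts <- str_split(dip, "/")[[1]]
      tibble(gene = g, allele_1 = parts[1], allele_2 = parts[2])
    })
    attr(dips, "bundle") <- bundle
    meds <- medication_record(
      panel_drug[i],
      route = if (panel_drug[i] == "tacrolimus") "topical" else "oral"
    )
    if (!is.na(inhibitor[i])) {
      meds <- bind_rows(meds, medication_record(inhibitor[i]))
    }
    make_patient(
      sprintf("P%02d", i), dips,
      cnv = if (i == n) "yes" else "no",
      medications = meds,
      demo_row = tibble(age = ages[i], sex = sex[i], race = race[i],
                        ethnicity = ethnicity[i])
    )
  })
}

#' Deterministic enrollment-funnel fixture
#'
#' Reconstructs the pilot's printed enrollment funnel: 244 patients
#' identified, 162 contacted, 17 excluded at contact (10 with no active panel
#' drug, 6 no longer plan-enrolled, 1 with prior testing), 145 confirmed
#' eligible, 110 agreed (50 on the initial call, 10 on a follow-up call, 47
#' by portal message, 3 in person) and 61 kits returned. Turnaround days for
#' returned kits are a deterministic spread centred near the pilot's reported
#' mean.
#'
#' @return Tibble of 244 funnel records.
#' @export
fixture_funnel_fig2 <- function() {
  n <- 244
  records <- tibble(
    sample_id = sprintf("F%03d", seq_len(n)),
    identified = TRUE,
    contacted = seq_len(n) <= 162,
    confirmed_eligible = seq_len(n) >= 18 & seq_len(n) <= 162,
    exclusion_reason = block_labels(
      c(10, 16, 17, n),
      c("no panel drug", "not plan-enrolled", "prior PGx test", ""), n
    ),
    agreed = seq_len(n) >= 18 & seq_len(n) <= 127,
    consent_channel = block_labels(
      c(17, 67, 77, 124, 127, n),
      c("none", "initial call", "follow-up call", "portal message",
        "in person", "none"), n
    ),
    kit_returned = seq_len(n) >= 18 & seq_len(n) <= 78,
    turnaround_days = NA_real_
  )
  records$exclusion_reason[records$confirmed_eligible |
                             !records$contacted] <- NA_character_
  records$exclusion_reason[records$exclusion_reason == ""] <- NA_character_
  returned <- which(records$kit_returned)
  records$turnaround_days[returned] <-
    pmax(round(stats::qnorm(stats::ppoints(length(returned)), 30.9, 14.6)), 7)
  records
}

#' Deterministic post-test survey fixture
#'
#' 24 responders: 20 describing the process as positive, 17 preferring an
#' appointment with a pharmacogenetics specialist, 6 perceiving a potential
#' impact on their care (so that whole-percent rounding reproduces the
#' pilot's printed 71% and 25%, and more than 80% positive).
#'
#' @return Tibble of 24 survey responses.
#' @export
fixture_survey_fig5 <- function() {
  n <- 24
  tibble(
    sample_id = sprintf("P%02d", seq_len(n)),
    overall_positive = seq_len(n) <= 20,
    prefers_specialist = seq_len(n) <= 17,
    perceived_impact = seq_len(n) <= 6
  )
}

#' Parameters for the stochastic cohort generator
#'
#' Defaults emulate the pilot cohort: per-gene allele frequencies chosen so
#' Hardy-Weinberg diplotype sampling reproduces the published phenotype
#' marginals in expectation, a 23% CYP2D6 inhibitor exposure rate (11/14
#' strong among the exposed), per-drug prescription rates mirroring the
#' pilot's most common panel drugs, and demographics with mean age 50.93
#' (SD 10.21).
#'
#' @param n Cohort size.
#' @param allele_freqs Named list (per gene) of named allele-frequency
#'   vectors, each summing to 1.
#' @param inhibitor_exposure_rate Probability a patient takes a CYP2D6
#'   inhibitor.
#' @param p_strong_given_exposed Probability the inhibitor is strong.
#' @param cnv_rate Probability of a detected CYP2D6 copy-number variation.
#' @param panel_drug_rates Named per-drug prescription probabilities.
#' @param age_mean,age_sd Age distribution (years).
#' @param sex_props,race_props,ethnicity_props Named proportion vectors.
#' @param seed Integer seed.
#' @return A `pgx_cohort_params` list.
#' @export
cohort_params <- function(n = 61,
                          allele_freqs = default_allele_freqs(),
                          inhibitor_exposure_rate = 14 / 61,
                          p_strong_given_exposed = 11 / 14,
                          cnv_rate = 1 / 61,
                          panel_drug_rates = default_panel_drug_rates(),
                          age_mean = 50.93, age_sd = 10.21,
                          sex_props = c(Female = 39, Male = 22) / 61,
                          race_props = c(White = 53, Asian = 3, Other = 3,
                                         `Black or African American` = 2) / 61,
                          ethnicity_props = c(`Not Hispanic or Latino` = 59,
                                              `Hispanic or Latino` = 1,
                                              `Unknown/Not Reported` = 1) / 61,
                          seed = 1L) {
  p <- list(n = n, allele_freqs = allele_freqs,
            inhibitor_exposure_rate = inhibitor_exposure_rate,
            p_strong_given_exposed = p_strong_given_exposed,
            cnv_rate = cnv_rate, panel_drug_rates = panel_drug_rates,
            age_mean = age_mean, age_sd = age_sd, sex_props = sex_props,
            race_props = race_props, ethnicity_props = ethnicity_props,
            seed = seed)
  validate_cohort_params(p)
  structure(p, class = "pgx_cohort_params")
}

#' Default per-gene allele frequencies for the cohort generator
#'
#' Chosen so Hardy-Weinberg sampling reproduces the pilot's phenotype
#' marginals in expectation (e.g. CYP3A5 *3 at 0.90 gives 81% poor
#' metabolizers).
#'
#' @return Named list of named allele-frequency vectors, one per panel gene.
#' @export
default_allele_freqs <- function() {
  list(
    CYP2C19 = c(`*1` = 0.72, `*2` = 0.13, `*17` = 0.15),
    CYP2D6 = c(`*1` = 0.92, `*4` = 0.05, `*41` = 0.03),
    CYP2C9 = c(`*1` = 0.77, `*2` = 0.15, `*3` = 0.08),
    CYP3A5 = c(`*1` = 0.10, `*3` = 0.90),
    SLCO1B1 = c(`*1` = 0.85, `*5` = 0.15),
    CYP4F2 = c(`*1` = 0.67, `*3` = 0.33),
    VKORC1 = c(G = 0.58, A = 0.42),
    `CYP2C-cluster` = c(G = 0.88, A = 0.12)
  )
}

#' Default per-drug prescription rates for the cohort generator
#'
#' Rates mirror the pilot's most common active panel drugs.
#'
#' @return Named numeric vector of per-drug prescription probabilities.
#' @export
default_panel_drug_rates <- function() {
  c(omeprazole = 14, tramadol = 9, escitalopram = 8, pantoprazole = 8,
    sertraline = 5, ibuprofen = 6, celecoxib = 3, meloxicam = 2,
    hydrocodone = 3) / 61
}

validate_cohort_params <- function(p) {
  probs <- c(p$inhibitor_exposure_rate, p$p_strong_given_exposed, p$cnv_rate,
             p$panel_drug_rates)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]", class = "pgx_input_error")
  }
  for (g in names(p$allele_freqs)) {
    f <- p$allele_freqs[[g]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
      abort(sprintf("allele frequencies for %s must be non-negative and sum to 1", g),
            class = "pgx_input_error")
    }
  }
  for (nm in c("sex_props", "race_props", "ethnicity_props")) {
    if (abs(sum(p[[nm]]) - 1) > 1e-8) {
      abort(sprintf("%s must sum to 1", nm), class = "pgx_input_error")
    }
  }
  invisible(p)
}

#' Simulate a cohort under Hardy-Weinberg diplotype sampling
#'
#' Each patient's two alleles per gene are drawn independently from the
#' gene's allele-frequency vector (random mating), converted to rsID-level
#' genotype calls; medications are drawn per-drug from the prescription
#' rates, with an optional CYP2D6 inhibitor added per the exposure rate;
#' demographics come from the stated distributions. Reproducible for a given
#' seed; the global RNG state is left untouched.
#'
#' @param params A `pgx_cohort_params` list (see [cohort_params()]).
#' @param bundle Reference bundle.
#' @return List of `pgx_patient` records (empty when `n = 0`).
#' @export
simulate_cohort <- function(params = cohort_params(),
                            bundle = load_reference_bundle()) {
  validate_cohort_params(params)
  if (params$n == 0) return(list())
  with_seed(params$seed, {
    map(seq_len(params$n), function(i) {
      dips <- purrr::imap_dfr(params$allele_freqs, function(freqs, g) {
        al_g <- bundle$alleles[bundle$alleles$gene == g, ]
        ref_g <- al_g$star_allele[lengths(al_g$variants) == 0][1]
        pair <- sample(names(freqs), 2, replace = TRUE, prob = freqs)
        pair <- sort_alleles(pair[1], pair[2], ref = ref_g)
        tibble(gene = g, allele_1 = pair[1], allele_2 = pair[2])
      })
      attr(dips, "bundle") <- bundle
      on_drug <- stats::runif(length(params$panel_drug_rates)) <
        params$panel_drug_rates
      meds <- if (any(on_drug)) {
        medication_record(names(params$panel_drug_rates)[on_drug])
      } else {
        empty_medications()
      }
      if (stats::runif(1) < params$inhibitor_exposure_rate) {
        inh <- if (stats::runif(1) < params$p_strong_given_exposed) {
          "fluoxetine"
        } else {
          "duloxetine"
        }
        meds <- bind_rows(meds, medication_record(inh))
      }
      cnv <- if (stats::runif(1) < params$cnv_rate) "yes" else "no"
      age <- max(18, round(stats::rnorm(1, params$age_mean, params$age_sd)))
      make_patient(
        sprintf("S%04d", i), dips, cnv, meds,
        tibble(
          age = age,
          sex = sample(names(params$sex_props), 1, prob = params$sex_props),
          race = sample(names(params$race_props), 1,
                        prob = params$race_props),
          ethnicity = sample(names(params$ethnicity_props), 1,
                             prob = params$ethnicity_props)
        )
      )
    })
  })
}

#' Parameters for the stochastic funnel generator
#'
#' Defaults are the pilot's stage rates: 66% contact, 145/162 confirmed
#' eligible at contact, 76% consent, 55% kit return, and a
#' truncated-at-zero normal turnaround with mean 30.9 and SD 14.6 days.
#'
#' @param n_identified Number of patients identified by record review.
#' @param p_contact,p_confirm_eligible,p_agree,p_return Stage probabilities.
#' @param exclusion_reason_mix Named proportions of exclusion reasons among
#'   contacted-but-ineligible patients.
#' @param consent_channel_mix Named proportions of consent channels among
#'   those who agreed (must sum to 1).
#' @param turnaround_mean,turnaround_sd Turnaround distribution (days).
#' @param seed Integer seed.
#' @return A `pgx_funnel_params` list.
#' @export
funnel_params <- function(n_identified = 244,
                          p_contact = 162 / 244,
                          p_confirm_eligible = 145 / 162,
                          exclusion_reason_mix = c(`no panel drug` = 10,
                                                   `not plan-enrolled` = 6,
                                                   `prior PGx test` = 1) / 17,
                          p_agree = 110 / 145,
                          consent_channel_mix = c(`initial call` = 50,
                                                  `follow-up call` = 10,
                                                  `portal message` = 47,
                                                  `in person` = 3) / 110,
                          p_return = 61 / 110,
                          turnaround_mean = 30.9,
                          turnaround_sd = 14.6,
                          seed = 1L) {
  p <- list(n_identified = n_identified, p_contact = p_contact,
            p_confirm_eligible = p_confirm_eligible,
            exclusion_reason_mix = exclusion_reason_mix,
            p_agree = p_agree, consent_channel_mix = consent_channel_mix,
            p_return = p_return, turnaround_mean = turnaround_mean,
            turnaround_sd = turnaround_sd, seed = seed)
  probs <- c(p$p_contact, p$p_confirm_eligible, p$p_agree, p$p_return)
  if (any(probs < 0 | probs > 1)) {
    abort("stage probabilities must lie in [0, 1]", class = "pgx_input_error")
  }
  if (abs(sum(p$consent_channel_mix) - 1) > 1e-8) {
    abort("consent_channel_mix must sum to 1", class = "pgx_input_error")
  }
  structure(p, class = "pgx_funnel_params")
}

#' Simulate an enrollment funnel as independent Bernoulli stages
#'
#' Each identified patient passes contact, eligibility confirmation, consent
#' and kit-return stages by independent draws at the stated rates; exclusion
#' reasons and consent channels are sampled from their mixes; turnaround days
#' are drawn for returned kits from a normal truncated at zero.
#'
#' @param params A `pgx_funnel_params` list (see [funnel_params()]).
#' @return Tibble of funnel records (same schema as [fixture_funnel_fig2()]).
#' @export
simulate_funnel <- function(params = funnel_params()) {
  n <- params$n_identified
  with_seed(params$seed, {
    contacted <- stats::runif(n) < params$p_contact
    confirmed <- contacted & stats::runif(n) < params$p_confirm_eligible
    excluded <- contacted & !confirmed
    agreed <- confirmed & stats::runif(n) < params$p_agree
    returned <- agreed & stats::runif(n) < params$p_return

    reason <- rep(NA_character_, n)
    if (any(excluded)) {
      reason[excluded] <- sample(names(params$exclusion_reason_mix),
                                 sum(excluded), replace = TRUE,
                                 prob = params$exclusion_reason_mix)
    }
    channel <- rep("none", n)
    if (any(agreed)) {
      channel[agreed] <- sample(names(params$consent_channel_mix),
                                sum(agreed), replace = TRUE,
                                prob = params$consent_channel_mix)
    }
    turnaround <- rep(NA_real_, n)
    k <- sum(returned)
    if (k > 0) {
      draws <- stats::rnorm(k, params$turnaround_mean, params$turnaround_sd)
      while (any(draws <= 0)) {  # truncate at zero by resampling
        bad <- draws <= 0
        draws[bad] <- stats::rnorm(sum(bad), params$turnaround_mean,
                                   params$turnaround_sd)
      }
      turnaround[returned] <- draws
    }
    tibble(
      sample_id = sprintf("F%04d", seq_len(n)),
      identified = TRUE,
      contacted = contacted,
      confirmed_eligible = confirmed,
      exclusion_reason = reason,
      agreed = agreed,
      consent_channel = channel,
      kit_returned = returned,
      turnaround_days = turnaround
    )
  })
}

#' Write a cohort's standard input files
#'
#' Serializes a cohort (fixture or simulated) to the pipeline's file formats:
#' `genotypes.tsv` (sample_id, rsid, allele_1, allele_2), `cnv.tsv`
#' (sample_id, cyp2d6_cnv), `medications.csv` (sample_id, drug, route,
#' active) and `demographics.csv` (sample_id, age, sex, race, ethnicity).
#'
#' @param cohort List of `pgx_patient` records.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_files <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genotypes <- purrr::map_dfr(cohort, function(p) {
    calls <- p$snp_calls$calls
    tibble(sample_id = p$sample_id, rsid = names(calls),
           allele_1 = map_chr(calls, 1), allele_2 = map_chr(calls, 2))
  })
  readr::write_tsv(genotypes, file.path(dir, "genotypes.tsv"))
  purrr::map_dfr(cohort, function(p) {
    tibble(sample_id = p$sample_id, cyp2d6_cnv = p$snp_calls$cyp2d6_cnv)
  }) |>
    readr::write_tsv(file.path(dir, "cnv.tsv"))
  purrr::map_dfr(cohort, function(p) {
    if (nrow(p$medications) == 0) return(NULL)
    bind_cols(tibble(sample_id = p$sample_id), p$medications)
  }) |>
    readr::write_csv(file.path(dir, "medications.csv"))
  purrr::map_dfr(cohort, function(p) p$demographics) |>
    readr::write_csv(file.path(dir, "demographics.csv"))
  invisible(dir)
}
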