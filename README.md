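# pgxpanel

Interpretation and cohort analytics for an eight-gene preemptive
pharmacogenetic (PGx) panel, written for implementation teams who need to
turn rsID-level genotype calls into clinically framed phenotype reports and
program-level metrics.

The panel covers *CYP2C19*, *CYP2D6*, *CYP2C9*, *CYP3A5*, *SLCO1B1*,
*CYP4F2*, *VKORC1* and the *CYP2C* cluster. The package implements the full
interpretation chain:

1. **Star-allele diplotype inference.** Each gene's alleles are defined by
   rsID-level variants. For a sample's genotype calls, the caller selects the
   allele pair whose combined defining-variant multiset exactly explains
   every observed variant allele; sites without an observed variant default
   to the reference (\*1) allele, mirroring the assay's behaviour. An
   unexplained or failed call makes the gene indeterminate.
2. **Phenotype translation per CPIC conventions.** CYP2D6 and CYP2C9 are
   labelled through the activity score
   AS = v(allele 1) + v(allele 2),
   with the legacy CYP2D6 cutoffs (AS = 0 → PM, 0 < AS < 1 → IM,
   1 ≤ AS ≤ 2 → NM, AS > 2 → UM; an AS of 1.0 is a normal metabolizer).
   CYP2C19, CYP3A5 and SLCO1B1 use diplotype lookups; VKORC1, CYP4F2 and the
   CYP2C cluster are reported as genotype strings. A detected CYP2D6
   copy-number variation leaves the gene indeterminate because the assay
   cannot resolve which allele is affected or the copy count.
3. **Phenoconversion.** A strong CYP2D6 inhibitor on the active medication
   list converts any metabolizer to a clinical poor metabolizer; a moderate
   inhibitor steps the label down one rank.
4. **Actionability.** Active medications are matched against a curated
   27-drug panel list (route-aware: topical tacrolimus is not a systemic
   exposure); a gene–drug pair is currently actionable when the clinical
   phenotype carries a guideline recommendation for a drug or dose change,
   and genotype profiles are screened for potential future actionability
   independent of current therapy.
5. **Cohort analytics and reporting.** Phenotype frequency tables,
   phenoconversion and actionability summaries, demographics,
   enrollment-funnel stage rates, post-test survey fractions, and
   per-patient pharmacist-style consult notes.

A synthetic-data module ships deterministic fixture cohorts reproducing a
61-patient pilot program's published marginals, plus stochastic generators
(Hardy–Weinberg diplotype sampling; Bernoulli-stage enrollment funnels) for
property-based testing at arbitrary size.

## Worked example

```r
library(pgxpanel)

bundle <- load_reference_bundle()

# A patient heterozygous for CYP2C19*2, on omeprazole and paroxetine
s <- snp_call_set("PT01", list(rs4244285 = c("G", "A")))
infer_diplotype(s, "CYP2C19", bundle)$diplotype
#> [1] "*1/*2"

patient <- list(sample_id = "PT01", snp_calls = s,
                medications = medication_record(c("omeprazole", "paroxetine")))
res <- interpret_patient(patient, bundle)
subset(res$phenotypes, gene %in% c("CYP2C19", "CYP2D6"),
       c(gene, diplotype, genotype_based_phenotype, clinical_phenotype))
#> # A tibble: 2 × 4
#>   gene    diplotype genotype_based_phenotype clinical_phenotype
#>   <chr>   <chr>     <chr>                    <chr>
#> 1 CYP2C19 *1/*2     IM                       IM
#> 2 CYP2D6  *1/*1     NM                       PM
res$actionability[, c("drug", "gene", "currently_actionable")]
#> # A tibble: 2 × 3
#>   drug       gene    currently_actionable
#>   <chr>      <chr>   <lgl>
#> 1 omeprazole CYP2C19 TRUE
#> 2 paroxetine CYP2D6  TRUE
```

The CYP2C19 intermediate metabolizer makes omeprazole actionable (the
guideline recommendation at that phenotype is a drug or dose change), and
paroxetine — a strong CYP2D6 inhibitor — both converts the genotypic normal
metabolizer to a clinical poor metabolizer and is itself actionable at that
clinical phenotype.

Cohort-level, on the deterministic fixture:

```r
cohort  <- fixture_cohort_table3(bundle)
results <- interpret_cohort(cohort, bundle)
report  <- cohort_report(results, funnel = fixture_funnel_fig2(),
                         survey = fixture_survey_fig5(), bundle = bundle)
report$phenoconversion[c("n_exposed", "n_converted", "pm_prevalence_after")]
#> $n_exposed [1] 14    $n_converted [1] 13    $pm_prevalence_after [1] 20
report$funnel$rates
#> $contact [1] 66     $consent [1] 76        $kit_return [1] 55
```

A command-line wrapper with `fixtures` / `interpret` / `cohort` / `simulate`
subcommands lives at `inst/cli/pgxpanel.R`.

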