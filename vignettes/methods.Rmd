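---
title: "Methods: panel interpretation, phenoconversion and cohort emulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel interpretation, phenoconversion and cohort emulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxpanel)
```

## The interpretation model

The package interprets an rsID-defined SNP panel over eight pharmacogenes.
Because the assay types a fixed list of sites rather than sequencing
haplotypes, the star-allele model is deliberately simple: every non-reference
allele is defined by a small set of `rsID = variant-allele` observations, and
a diplotype is the unordered pair of alleles whose combined defining-variant
multiset *exactly* explains the variant alleles observed at the gene's
defining sites.

Three consequences of that design are worth stating explicitly:

* **Default-to-reference.** A site at which no variant allele is observed —
  including sites absent from the call set entirely — contributes nothing to
  the observation multiset, so a patient with no observed variants is called
  reference/reference (\*1/\*1). This mirrors the assay's own behaviour and
  shares its known limitation: a variant the panel does not type is invisible,
  and the carrier is labelled a normal metabolizer.
* **Missing is different from reference.** A site explicitly recorded as
  `missing` represents an assay failure, not a reference observation. Any
  missing call at a defining site makes the gene indeterminate, which then
  propagates through phenotype assignment, phenoconversion (an indeterminate
  phenotype never converts) and actionability (an indeterminate phenotype
  triggers nothing).
* **No phasing.** Heterozygous calls at two sites defining different alleles
  are assigned in trans, one per chromosome. With one defining site per
  allele, cis configurations are unrepresentable, so this loses nothing.

When two allele pairs explain the observations equally well, the matcher
prefers the pair with fewer variant-defined alleles (the reference-biased
choice, consistent with default-to-reference), then the smallest star
numbers; the alternatives are kept in `ambiguity_note`. With the shipped
one-site-per-allele definitions ties cannot actually arise — the rule exists
so that user-supplied multi-site definitions behave predictably. The test
suite checks the matcher against a brute-force oracle that enumerates all
ordered allele pairs and scores exact explanation, over randomized call sets
covering every gene.

The shipped allele definitions are representative of an rsID panel of this
design, not a byte-exact copy of any vendor's assay sheet: each allele is
keyed to its canonical defining rsID (e.g. CYP2C19\*2 to rs4244285,
CYP2D6\*41 to rs28371725, SLCO1B1\*5 to rs4149056). Multi-site haplotype
subtleties (e.g. CYP2D6\*41 arising on a \*2 background) are out of scope of
the single-site model and are documented as such rather than half-modelled.

## Phenotype translation

CYP2D6 and CYP2C9 are translated through the activity score, the sum of the
two alleles' activity values. CYP2D6 uses the *legacy* cutoff scheme under
which a score of 1.0 is a normal metabolizer:

| activity score | phenotype |
|---|---|
| 0 | PM |
| 0 < AS < 1 | IM |
| 1 ≤ AS ≤ 2 | NM |
| > 2 | UM |

The map is shipped as data (`cutoffs.json`, half-open `[lower, upper)`
intervals) and validated to partition `[0, ∞)`; the interval edges (0.25 and
2.25) fall between realizable scores, so the boundaries above are exact.
CYP2C9 uses a fixed score map (AS < 1 → PM, 1 ≤ AS < 2 → IM, AS ≥ 2 → NM).
CYP2C19, CYP3A5 and SLCO1B1 use diplotype lookups generated from allele
function classes (two no-function alleles → PM, one → IM, increased-function
combinations → RM/UM; any functional CYP3A5 allele → expresser/NM; SLCO1B1
reported as normal/decreased/poor function). VKORC1, CYP4F2 and the CYP2C
cluster carry no metabolizer semantics at the panel level and are reported
as genotype strings (`G/A`, `*1/*3`).

CYP3A5 deserves a note: the shipped lookup reports two categories (any \*1
allele → NM, otherwise PM), matching the two-category reporting the fixture
cohort reproduces. CPIC's three-category scheme (which calls \*1/\*3 an
intermediate metabolizer) can be obtained by editing the shipped allele
table — the lookup is generated from function classes, not hard-coded.

A detected CYP2D6 copy-number variation makes the activity score — and
therefore the phenotype — indeterminate, because the assay detects *that* a
CNV exists but not which allele is affected nor how many copies are present.

## Phenoconversion convention

Phenoconversion is applied to CYP2D6 only, from the strongest active,
systemically administered inhibitor on the medication list (topical routes
are ignored):

* **strong** inhibitor → clinical poor metabolizer, regardless of genotype;
* **moderate** inhibitor → one phenotype-rank step down (UM→NM, NM→IM,
  IM→PM, PM stays PM);
* **none** → unchanged.

The moderate rule steps the *label* rather than halving the activity score.
Under the legacy cutoffs, score-halving would leave a two-functional-allele
normal metabolizer (AS 2 → 1) still normal, i.e. moderate inhibitors could
never convert the most common genotype — contradicting observed
moderate-inhibitor conversions. The label-step rule is the weakest
convention that converts every non-floor phenotype by exactly one rank.
Two invariants are enforced by exhaustive tests: conversion never raises the
phenotype rank, and strong conversion is idempotent.

## Actionability

A gene–drug pair is *currently actionable* when the clinical phenotype is in
the drug's actionable set — the phenotypes for which the guideline
recommendation is a drug or dose change. The shipped rule table encodes the
pilot-era guidance: proton pump inhibitors actionable for CYP2C19 PM/IM/UM
(with NM/RM flagged as potentially actionable in the future based on
indication), rabeprazole retained on the panel list, opioids and tricyclics
for CYP2D6 PM/IM/UM, NSAIDs for CYP2C9 PM/IM, tacrolimus for CYP3A5
expressers, simvastatin for decreased/poor SLCO1B1 function, and so on. The
evidence grades (strong/moderate/optional) are guideline-derived defaults in
an editable table; only the "at least moderate" distinction is consumed
downstream. *Potential* actionability is computed from genotype-based
phenotypes against all rules for the gene, regardless of current therapy.

The panel list totals exactly 27 distinct drugs — enforced as a validation
invariant — of which 14 are the published pain/mental-health rows; the
remainder are the guideline drugs for the panel genes (remaining PPIs,
tacrolimus, warfarin, clopidogrel, voriconazole, simvastatin, amitriptyline,
nortriptyline). Eligibility screening applies the pilot's four inclusion
criteria (age ≥ 18, plan enrollment, ≥ 1 active panel drug regardless of
therapy duration, a visit within 12 months) plus the prior-testing
exclusion, reporting every failed criterion.

## What the fixtures emulate — and what they cannot

`fixture_cohort_table3()` rebuilds a 61-patient cohort whose *per-gene*
phenotype marginals equal the pilot's published table, realized as
representative diplotypes (CYP2C19 PM as \*2/\*2, RM as \*1/\*17; CYP2D6 PM
as \*4/\*4, IM as \*4/\*41; patient 61 CNV-flagged and hence indeterminate).
Labels are assigned in contiguous index blocks anchored at patient 1.
Because only marginals were published, *any* joint structure across genes is
admissible; blocks are the auditable choice. The consequence is documented
rather than hidden: joint-distribution figures (the published "nearly 89%"
potential-actionability fraction, the 23 currently actionable pairs, the 86
active prescriptions) depend on unpublished per-patient genotype–medication
combinations and are deliberately not reproduced. The counting and
monotonicity invariants of the actionability module are tested in their
place.

Inhibitor exposure follows the published pattern: 14 exposed, of whom 13
convert. The assignment — 11 on a strong inhibitor and 2 on a moderate one,
all genotypic NMs, plus a moderate inhibitor on the genotypic PM — is the
minimal configuration consistent with 13 conversions and a clinical PM
prevalence rounding to 20% (12/61). The published account does not say which
exposed patient failed to convert; the fixture assigns the genotypic PM, the
rank floor, as the only choice under the conversion rules that cannot
convert. Strong and moderate inhibitors are realized as fluoxetine and
duloxetine — drugs that are not themselves panel drugs — so that exposure
does not perturb the panel-drug actionability counts.

The funnel fixture encodes the printed attrition (244 → 162 → 145 → 110 →
61, with the 17 exclusions and four consent channels); the survey fixture's
24 responses (20/17/6 affirmative) are the counts whose half-up
whole-percent rounding reproduces the printed 71% and 25% and exceed 80%
positive. Ages are a deterministic normal spread (mean 50.93, SD 10.21)
clamped to the published 25–71 range.

## Stochastic generators

`simulate_cohort()` draws each patient's two alleles per gene independently
from allele-frequency vectors (Hardy–Weinberg random mating), then converts
diplotypes to rsID calls, so simulated data exercise the *full* pipeline
from raw calls. Default frequencies are chosen to reproduce the fixture
marginals in expectation (e.g. CYP3A5 \*3 at 0.90 → 81% PM). Medications are
per-drug Bernoulli draws at the pilot's prescription rates; inhibitor
exposure at 14/61 with 11/14 strong. `simulate_funnel()` treats stages as
independent Bernoulli draws and samples turnaround from a normal truncated
at zero by resampling; the published long tail of kit returns (outliers of
3–4 months) is heavier than a truncated normal, so the distribution is a
parameter, not a claim. Every generator takes an explicit integer seed,
seeds a local RNG and restores the global RNG state on exit.

What passing tests show — and do not show — about real data: the generators
emulate marginal frequencies and independent-stage attrition. They do not
emulate linkage between genes, correlated prescribing (a patient on one PPI
is likelier to be on a second acid suppressant), EHR medication-list
inaccuracy, or informative missingness in genotype calls. Pipeline
correctness on simulated data is therefore evidence about the *computation*,
not about clinical performance.

## Numerical choices

* **Rounding.** Printed clinical percentages use arithmetic half-up
  rounding, not banker's rounding: whole percents generally, one decimal for
  fractions below 5% (so 1/61 prints as 1.6). Percentages of roughly 1/61
  printed elsewhere as 1.5% cannot be produced by any standard rounding of
  1/61 and are treated as a presentation discrepancy, never computed.
* **Interval maps** are half-open `[lower, upper)`, validated to partition
  `[0, ∞)` with no gaps or overlaps; the legacy requirement that AS 1.0 maps
  to NM is itself a validation rule.
* **Degenerate inputs.** Empty cohorts yield empty frequency tables (n = 0)
  but demographics of an empty cohort are an error; zero survey responders
  yield `NA` percents flagged by `n_responders = 0`; funnel records failing
  stage monotonicity are rejected naming the offending sample.
* **Problem sizes in tests** were chosen to make the statistical checks
  sharp at interactive cost: 1,000 random call sets for the oracle
  comparison, n = 2,000 with 99% binomial bands for Hardy–Weinberg recovery,
  n = 10,000 with a 3-standard-error band for funnel completion.

## Known limitations

* Single-site allele definitions cannot represent multi-SNP haplotypes,
  CYP2D6 hybrid/tandem arrangements, or which allele a CNV affects.
* Phenoconversion is binary in strength and CYP2D6-only; inducers, dose
  dependence and CYP2C19 phenoconversion (e.g. by PPIs) are out of scope.
* Actionability is a binary flag plus evidence grade; no dosing calculators.
* The drug→class map and evidence grades are editable defaults, not
  assertions about any particular guideline edition.
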