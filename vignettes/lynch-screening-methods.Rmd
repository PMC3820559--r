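---
title: "Universal Lynch-syndrome screening for endometrial cancer: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Universal Lynch-syndrome screening for endometrial cancer: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lynchscreen)
```

## The screening problem

Lynch syndrome (LS) is an autosomal-dominant cancer predisposition caused by
germline mutations in the mismatch-repair (MMR) genes *MLH1*, *MSH2*,
*MSH6* and *PMS2* (or by *EPCAM* deletions silencing *MSH2*). Endometrial
cancer (EC) is a sentinel tumor for LS: in roughly half of affected women it
precedes any colorectal cancer, so recognising LS at EC diagnosis enables
surveillance and prevention for the patient and her relatives. Universal
(age-unrestricted) tumor screening triages every newly diagnosed EC through
three tumor assays:

1. **Microsatellite instability (MSI)** over five mononucleotide markers
   (BAT26, BAT25, NR21, NR24, NR27); instability at two or more markers
   calls the tumor MSI.
2. **MMR immunohistochemistry (IHC)** for the four proteins; loss of nuclear
   staining (with an internal positive control) marks the inactivated gene.
3. **MLH1 promoter methylation** by MS-MLPA, for MLH1-deficient tumors only:
   somatic promoter hypermethylation explains most MLH1 loss and marks those
   tumors sporadic, removing them from germline work-up.

A tumor is **MMR-deficient** when it is MSI and/or shows any IHC loss. The
decision tree then maps each deficient tumor to a sporadic or suspected-LS
label and, for suspected cases, an ordered germline gene-testing plan.
Cohort-level accounting turns per-patient decisions into the screening
funnel (screened, deficient, methylated, suspected, tested, confirmed) and
prevalence estimates.

This package implements that pipeline end to end, together with a
deterministic reference cohort reproducing a published 173-patient
universal-screening series and a seeded simulator for property testing.

## Assay calls

### MSI

`call_msi()` counts unstable markers: two or more give MSI regardless of
marker failures. Failed markers are excluded from the informative count.
The published rule is silent about mostly-failed panels, so we add a guard:
an MSS call requires at least `min_informative = 3` informative markers;
otherwise the call is `indeterminate`. This prevents a false MSS on a panel
where, say, four markers failed and one was stable — a configuration that
does not occur in the reference cohort, so the guard never changes its
results. MSI can still be called with only two informative markers if both
are unstable, because instability is positive evidence.

### IHC

`call_ihc_pattern()` returns the set of lost proteins. A stain without a
working internal control is `unreliable` and is **never** counted as loss;
a panel whose every stain is unreliable yields an empty loss set with the
`any_unreliable` flag raised, and the MMR status then rests on MSI alone.
There is no rescue protocol because the underlying assay offers none.

### MLH1 methylation

`methylation_ratio()` averages the two promoter probes (MLH1-3, C region;
MLH1-4, D region). With a single available probe the ratio is that probe's
value and a warning records the single-probe call. `call_methylation()`
compares the ratio with a threshold of 0.15 (15%): the boundary is
inclusive (a ratio of exactly 0.15 is *methylated*) so that the stated
threshold value is itself actionable. Probe ratios up to 1.5 are accepted —
MS-MLPA normalisation can overshoot 1 — with a warning above 1.5 rather
than an error, since an implausibly high ratio still unambiguously means
"methylated".

## The decision tree

`triage_patient()` fires rules in a fixed order, each recorded in a
rationale trail (R1–R7; E1/E2 for unresolvable/pending states):

| rule | condition | outcome |
|------|-----------|---------|
| R1 | MMR proficient | no action |
| R2 | MLH1 lost, tumor methylated | sporadic (epimutation suspected if blood also methylated) |
| R3 | MLH1 lost, tumor unmethylated | suspected; test MLH1 |
| R4 | MSH2 lost | suspected; test MSH2 → MSH6 → EPCAM |
| R5 | MSH6 lost, MSH2 retained | suspected; test MSH6 |
| R6 | PMS2 lost, MLH1 retained | suspected; test PMS2 |
| R7 | MSI, no IHC loss | suspected; test MLH1 → MSH2 → MSH6 → PMS2 |

Design choices where the published description left room:

* **MSI with intact IHC (R7).** IHC gives no gene to start from, and both
  germline-diagnosed cases of this kind in the reference series reached a
  diagnosis, so the plan must span the panel; we order it by gene prevalence
  in LS (MLH1, MSH2, MSH6, PMS2).
* **EPCAM position (R4).** *EPCAM* rearrangement testing is described as
  following negative MSH2 and MSH6 sequencing; we encode the chain
  MSH2 → MSH6 → EPCAM. Whether MSH6 strictly preceded EPCAM is not stated.
* **Combined MSH6 + PMS2 loss.** R5 and R6 both fire and their plans merge
  to [MSH6, PMS2], in that order.
* **Blood methylation is optional.** A methylated tumor without a blood
  sample is labelled sporadic with a `"blood unconfirmed"` note — in the
  reference series only 9 of 34 methylated cases had blood analysed, all
  negative, and constitutional MLH1 epimutations in EC are rare.
* **MLH1 loss co-occurring with MSH2/MSH6 loss** (never observed in the
  reference series): the MLH1 branch takes precedence, so methylation is
  always resolved first. A methylated tumor is labelled sporadic even with
  co-occurring loss; an unmethylated one is suspected and R4 appends its
  chain after MLH1.
* **Pending, not defaulted.** MLH1 loss without a tumor methylation
  measurement yields `pending_methylation`; an indeterminate MSI call with
  no IHC loss yields `unresolvable`. Neither is ever silently coerced to a
  substantive label.

`next_gene()` walks a suspected patient's plan: a gene is tested only after
every earlier plan gene returned negative, and any pathogenic result closes
the plan. A variant of unknown significance (VUS) halts the automated plan:
whether to continue sequencing after a VUS is a clinical-review decision,
not a rule we are prepared to hard-code.

`two_antibody_triage()` implements the economical PMS2 + MSH6 comparator:
because PMS2 and MSH6 are the degradation-prone partners of the MLH1–PMS2
and MSH2–MSH6 heterodimers, loss of any of the four proteins is expected to
surface in one of these two stains. On the reference cohort (which encodes
heterodimer co-loss) it flags exactly the patients with any IHC loss.

## Cohort statistics

* **Odds ratios.** `odds_ratio_woolf()` uses the log-OR normal (Woolf)
  interval, `exp(log(ad/bc) ± z_{1-α/2}·√(1/a+1/b+1/c+1/d))`, with
  `z_{0.975} = 1.959964`. `odds_ratio_exact()` inverts the tails of
  Fisher's noncentral hypergeometric distribution at α/2 per side — the
  construction behind `fisher.test()`'s interval — and reports the
  cross-product point estimate alongside the conditional MLE. The
  machinery is written against the continuous (lgamma) extension of the
  binomial coefficients so that Haldane–Anscombe-corrected (non-integer)
  tables are handled uniformly; `fisher.test()` serves as an independent
  cross-check in the tests, not as the implementation. `odds_ratio()`
  auto-selects: Woolf for well-filled tables, exact when any cell is
  below 5, where the normal approximation degrades.
* **Zero cells.** Woolf intervals error on zero cells unless the
  Haldane–Anscombe +0.5 correction is explicitly requested; the correction
  is never applied silently and is recorded in the result.
* **Chi-squared.** The uncorrected Pearson statistic
  `n(ad−bc)²/((a+b)(c+d)(a+c)(b+d))` on 1 df. No Yates continuity
  correction by default: the reference study's significant age comparison
  (p = 0.04) is only reproduced without it (Yates gives ≈ 0.07). The
  corrected statistic is available behind `correct = TRUE`.
* **t-test from summary statistics.** `t_test_summary()` implements the
  pooled-variance two-sided Student t-test from (mean, sd, n) pairs — the
  only form computable from a published summary table; df = n₁ + n₂ − 2.
* **Cascade.** `cascade_summary()` tallies the funnel; conservation holds
  by construction: deficient = sporadic-methylated + epimutation-suspected
  + suspected (+ pending). `predictive_frequency()` corrects the observed
  prevalence for testing attrition by assuming untested suspected patients
  carry mutations at the tested patients' rate:
  `(n_suspected × n_pathogenic / n_tested) / n_total`.
* **Rounding.** Percentages quoted at printed precision use half-up
  rounding (`round_half_up()`), matching how clinical tables are printed;
  base R's half-to-even would differ on exact ties.

## The reference cohort

`paper_fixture()` builds, without randomness, a 173-patient cohort whose
margins equal the published screening series: 58 tumors with IHC loss and
47 with MSI (61 deficient; 14 loss-with-MSS and 3 MSI-with-intact-IHC
discordances), 44 with MLH1 loss of which 34 tumor-methylated (9 with blood
analysed, all negative), 27 suspected in the published per-pattern counts
(10/5/7/1/1/3), 19 tested and 8 pathogenic carriers with their published
identifiers, ages, MSI status, IHC patterns, genes and variant labels, plus
the clinical-table margins (stage, histology, grade, myometrial invasion,
lymphocytic infiltration, lymphovascular invasion, lower uterine segment,
synchronous ovarian cancers, family-history criteria) at their published
denominators.

Details the publication reports only in aggregate are fixed
deterministically, lowest patient index first, and are package choices:

* Which IHC-loss tumors are MSS: the two published MSS carriers and the two
  MSS VUS cases account for 4 of the 14; the remaining 10 are placed in the
  MLH1-methylated sporadic group.
* Heterodimer co-loss conventions: MLH1 loss is encoded as MLH1+PMS2,
  MSH2 loss as MSH2+MSH6 (matching the carriers' published patterns).
* Family-history criteria: the four Amsterdam-II patients are encoded as
  also fulfilling the revised Bethesda guidelines. This reconciles the
  published exclusive-category table (38 Bethesda-only, 4 Amsterdam II,
  45 neither, of 87 evaluable) with the published statement that 42
  patients (48.3%) fulfilled Bethesda.
* Non-carrier ages are fixed integer sequences chosen so the suspected
  group's mean is exactly 57.70 years (7 suspected patients under 50) and
  the non-suspected group's 64.31 (16 under 50), within the published
  29–90 range.
* One source table lists 26 synchronous ovarian cancers while the
  comparison table's cells sum to 27 of 152; the fixture follows the
  comparison-table cells, which feed the odds ratio.

## The simulator

`simulate_cohort()` draws patients through the hierarchy
deficiency → pattern → methylation → testing attrition → germline outcome,
with `default_params()` set to the published frequencies (61/173 deficient,
44/61 MLH1 loss among deficient, 34/44 methylated, 19/27 tested, 8/19
pathogenic, 14/58 loss-with-MSS discordance) and the published group age
moments (57.70 ± 12.45 suspected, 64.31 ± 12.12 otherwise, truncated to
29–90 by resampling). Assay observations are drawn so the calls reproduce
the assigned category: methylated tumors get probe ratios in [0.18, 0.80],
unmethylated in [0, 0.10]; MSI tumors get 2–5 unstable markers.

What the simulator emulates: the joint frequencies of deficiency, loss
patterns, methylation, discordance, attrition and yield, and group-specific
age distributions. What it does not: somatic biallelic inactivation or any
other mechanism behind mutation-negative deficiency, variant-level
genotypes, correlated pathology covariates, marker-specific instability
propensities, or between-pattern differences in discordance (a single
loss-with-MSS rate is applied to every loss pattern). Passing recovery
tests therefore demonstrates internal consistency of the pipeline under
the stated generative model, not calibration against real-world EC
cohorts.

## Problem sizes and numerical choices in the tests

The test suite enumerates the full decision-tree input space (3 MSI states
× 16 loss subsets × 9 methylation combinations), checks the statistics
against independent oracles (`chisq.test`, `fisher.test`, `t.test` on
vectors reconstructed to exact moments) on randomized small tables, and
runs parameter recovery over 200 simulated cohorts of 173 patients at the
default parameters, requiring the mean observed prevalence to lie within 3
Monte-Carlo standard errors of the hierarchical expectation (8/173).
Exact-interval comparisons against `fisher.test()` use a 2% tolerance on
the upper bound: `fisher.test()` solves its bounds with a much coarser
root-finder tolerance than this package's 1e-10 on the log-odds scale, and
the discrepancy is theirs, not ours. Root finding brackets log ψ by
doubling and solves with `uniroot`; conditional distributions are
normalised by max-subtraction to avoid overflow.

## Limitations

* The pipeline classifies; it does not assess variant pathogenicity
  (ACMG/InSiGHT), pedigree structure beyond the two boolean family-history
  flags, or cost-effectiveness.
* The predictive frequency assumes untested suspected patients carry
  mutations at the tested patients' rate — an extrapolation, not an
  estimate with a standard error.
* BRAF testing, useful in colorectal triage, is deliberately absent: it has
  no role in EC screening.
* The reference cohort is one hospital's consecutive series; its
  frequencies (and the simulator defaults derived from them) need not
  transfer to other populations.
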