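---
title: "Selecting SNPs by diagnostic performance metrics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting SNPs by diagnostic performance metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmetrics)
```

## The problem and the approach

Genome-wide association scans conventionally rank markers by association
P-value. For a late-onset Alzheimer's disease (LOAD) case-control study, a
P-value rank is a poor proxy for clinical usefulness: a marker can be
statistically unimpressive in a small training set yet carry worthwhile
screening characteristics, and the P-value threshold after multiple-testing
correction (Bonferroni `alpha / m`, about `1e-7` for half a million SNPs) is
rarely reached in modestly sized samples. `snpmetrics` implements the
alternative this package is built around: treat each SNP, under a dominant
genetic model, as a binary diagnostic test for case status and judge it by
its *performance metrics*.

For a SNP oriented to its minor allele, a sample is marker-positive when it
carries at least one minor allele. Cross-tabulating marker positivity with
case status gives TP, FP, FN, TN, from which ten metrics are computed:

* sensitivity `TP/(TP+FN)` and specificity `TN/(FP+TN)`;
* Youden index `sensitivity + specificity - 1`;
* predictive values `PPV = TP/(TP+FP)`, `NPV = TN/(FN+TN)`;
* diagnostic odds ratio `DOR = (TP*TN)/(FP*FN)`;
* accuracy `(TP+TN)/n`;
* net sensitivity and net specificity of *simultaneous (parallel) testing*
  of the SNP together with APOE e4 carrier status: a subject is combined
  positive if either marker is positive, so under conditional independence
  given disease status the combined operating characteristics are
  `net_sens = s_A + s_B - s_A s_B` and `net_spec = sp_A * sp_B`;
* AUC of a logistic model containing the SNP plus forced covariates (see
  below).

Markers are then ranked by the *metric-count rule*
(`select_by_metric_counts()`): for each candidate, count the metrics in
which it attains the maximum over all candidates (ties at the maximum all
count), rank by count, and break ties by mean metric rank, then AUC, then
P-value, then SNP id. The P-value ranking (`select_by_pvalue()`, keeping
boundary ties) is computed alongside for comparison.

The two-stage design is: select `k = 5` SNPs in a small, tightly matched
training set (stage 1); re-examine them in an independent validation set
(stage 2); force APOE e4 into the final model; convert the final logistic
coefficients into an integer point score; and report risk-group odds ratios
and an optimism-corrected AUC.

## Statistical components and their assumptions

**Hardy-Weinberg exact test** (`hwe_exact_test()`). Quality control removes
SNPs whose control genotypes are incompatible with Hardy-Weinberg
proportions. Conditional on the observed allele counts the heterozygote
count has a known discrete distribution; the two-sided exact P-value sums
the probabilities of all heterozygote counts no more probable than the
observed one. We compute the conditional probabilities by the standard
two-directional recurrence from the mode and normalize, which is numerically
stable for any sample size; tests verify it against an independent
log-gamma enumeration to 1e-12. A chi-square variant (`hwe_chisq_test()`) is
provided for comparison only; the exact test is what `apply_qc()` uses,
matching the convention of standard GWAS toolkits.

**QC cascade** (`apply_qc()`). Filters run in a fixed order: non-autosomal
SNPs; samples with genotyping success rate below 0.90; SNPs with call rate
below 0.98; SNPs with minor allele frequency below 0.05; SNPs with control
HWE exact P below 1e-4. MAF and HWE are computed in controls by default
(the subset for MAF is configurable, as published analyses do not always
state it). The cascade is idempotent and every removal is tallied so report
totals reconcile.

**Association statistics.** `snp_chisq()` offers the 1-df Pearson chi-square
without continuity correction on either the allele-count table (default) or
the dominant carrier table; which one a published scan used is often
unstated, so both are first-class. Adjusted odds ratios come from logistic
models: unconditional fits use IRLS through `stats::glm.fit`; matched-set
and age-stratum analyses use the exact conditional likelihood through
`survival::coxph`, whose stratified, unit-time, exact-method form is the
classical conditional-logistic trick. Strata without both a case and a
control carry no information and are dropped with a message. Coefficients
larger than 15 in absolute value are treated as evidence of separation and
flagged rather than reported as converged, a real concern in a 94-sample
training set with strong markers.

**Per-SNP AUC.** Published per-marker AUC columns in this design are nearly
constant across SNPs and far above what a single SNP can achieve alone,
implying a covariate-bearing model. We therefore define the per-SNP AUC as
the apparent AUC of an unconditional logistic model with the SNP carrier
indicator plus forced covariates (age > 75, female sex, education <= 6
years, APOE e4 carrier). This is a documented modelling choice; with strong
covariates the AUC column mostly measures the covariates, and the
SNP-specific discrimination lives in the other nine metrics.

**Point model** (`derive_points()`). Each dichotomous coefficient is divided
by the reference coefficient — sex, the smallest positive dichotomous
coefficient in the final model — and rounded *half-up to the nearest
integer*; the reference predictor scores 1. Nearest-integer rounding, not
ceiling, is the convention adopted here: with the published final-model
coefficients (2.42, 0.37, 2.11, 0.91, 0.64) it yields points (7, 1, 6, 2, 2)
and a 0-18 score range, whereas a ceiling would turn 0.91/0.37 = 2.46 into 3
and break the published score range. Risk groups default to low 0-6,
moderate 7-11, high 12-18; group odds ratios use indicator terms with the
low group as reference, and the trend P-value is a Wald test on the group
entered as an ordinal 0/1/2 score.

**AUC and internal validation.** `auc_delong()` computes the Mann-Whitney
AUC (ties counted one half) with a DeLong confidence interval via
\pkg{pROC}; tests verify the point estimate against an explicit pairwise
oracle. `loocv_optimism()` refits the model once per left-out sample and
pools the out-of-fold scores into a cross-validated AUC. Optimism is
defined as apparent minus cross-validated AUC, so the optimism-corrected
AUC *is* the cross-validated AUC; the identity is asserted on every run.
Bootstrap-style validation is intentionally out of scope.

## The synthetic study generator

`simulate_study()` exists so every downstream stage is testable without
access to any real genotypes. It emulates a two-stage LOAD case-control
study:

* a source population (default 50 times the requested cases) with age
  ~ Normal(75, 6^2) truncated at 65, 55% women, a three-component education
  mixture giving about 35% with <= 6 years, BMI ~ Normal(23.5, 3^2), 25%
  ever-smokers, and binary comorbidity flags — values chosen to resemble
  published elderly Taiwanese case-control demographics, since exact
  distributions are not identifiable from summary tables;
* independent biallelic autosomal SNPs in Hardy-Weinberg proportions with
  MAFs uniform on (0.05, 0.5);
* five causal SNPs with dominant odds ratios 9, 8, 7, 6, 5 at MAFs 0.12,
  0.20, 0.45, 0.49, 0.50 — spanning the adjusted-odds-ratio magnitudes and
  the control MAFs reported for validated LOAD markers, and comfortably
  inside the MAF >= 0.05 filter;
* an APOE-like locus: two haplotypes per subject drawn i.i.d. from
  {e2, e3, e4} with frequencies (0.08, 0.84, 0.08); e4 marks the minor
  allele of an rs429358-like SNP, e2 of an rs7412-like SNP; carrier odds
  ratios 3.5 (one e4) and 17.7 (two e4), the values reported for this
  population;
* covariate effects on the log-odds scale taken from the published final
  model (age > 75: 2.42; female: 0.37; education <= 6 years: 2.11);
* disease assigned by a logistic model whose intercept is *calibrated by
  root-finding so the realized population prevalence equals
  `baseline_prevalence`* (default 0.05, a realistic LOAD prevalence in the
  elderly). A raw `qlogis(0.05)` intercept plus effects of this magnitude
  would put most of the population above 50% risk, which is both
  unrealistic and destructive: the saturated logistic washes out marginal
  genotype contrasts;
* retrospective sampling of the configured cases and controls per stage
  (defaults 55/39 and 196/423), with stage-1 subjects drawn from the
  restricted subpopulation (18.5 < BMI < 27, never-smokers) so the stage-1
  sizes are the sizes entering matching; genotype missingness injected at
  rate 0.005.

Because non-causal SNPs are independent of disease by construction, they
are simulated only for the sampled individuals, which keeps a
2000-SNP study fast without changing any distribution.

**What the generator does not emulate.** Linkage disequilibrium (SNPs are
independent given the haplotype locus; the published population showed only
weak LD between the APOC1-like SNP and APOE, D' = 0.6, R^2 = 0.012, so no LD
is the defensible default), population stratification, genotyping batch
effects, differential missingness, and genome-scale (500k) marker counts.
Passing tests on this generator therefore demonstrate correctness of the
statistical machinery and calibration under idealized sampling — not
robustness to the artefacts of real microarray data.

## Matching

Stage-1 cases and controls are matched by `restrict_and_match()`: after the
BMI and smoking restrictions, each case (in stable id order) takes the
eligible control — exact match on sex by default, age within 5 years —
minimizing the age difference, ties broken by control id. An unused control
is always preferred; only when a case has no unused eligible control is a
control reused. Reuse-as-fallback matters: a naive nearest-age greedy match
with unrestricted reuse funnels most cases onto a handful of controls,
which collapses the distinct-control count and ruins specificity
estimation, whereas published matched designs of this shape use almost
every control once and reuse a few. Comorbidity flags can be added to
`exact_match_vars`, but with a control pool fixed at 39 subjects, exact
matching on four binary flags drops about a quarter of cases, so it is not
the default. Matched sets feed the stage-1 conditional logistic fits; each
distinct individual contributes once to metrics and QC.

## Numerical choices and degenerate inputs

* Metric comparisons in the count rule round to 6 decimals first, so float
  noise cannot manufacture a unique maximum.
* A DOR with an empty cell is flagged (`Inf` when `FP*FN = 0`, `NA` when
  `TP*TN = 0` too) and excluded from the DOR comparison in the count rule:
  an infinite flag is not a comparable magnitude, and at genome scale some
  null SNP always has an empty cell.
* Undefined metrics (empty margins) are `NA` and flagged, never silently 0.
* Marker orientation stays fixed to the minor allele even when the Youden
  index is negative; protective markers keep their negative Youden rather
  than being flipped, matching how published tables report them.
* Minor-allele frequency ties at 0.5 break lexicographically by allele
  character, making file parsing deterministic.
* HWE exact P-values compare probabilities with a `1 + 1e-10` relative
  guard so equal-probability configurations are included in the tail.
* All randomness flows from a single integer seed; identical seeds give
  byte-identical study objects and pipeline reports.

## Known limitations

* The genome-wide metric-count rule is noisy at training-set sizes of ~100
  subjects: the maxima of specificity and PPV are typically claimed by
  rare-MAF null SNPs with nearly empty carrier cells, so planted causal
  SNPs are strongly *enriched* near the top of the ranking but are not
  guaranteed to monopolize the top 5. Interpreting the rule as a shortlist
  generator (take the top ranking and validate in stage 2) matches how it
  behaves.
* Exact recovery of a published integer point vector from refitted
  coefficients is unstable by construction: points divide by the sex
  coefficient, whose own standard error at n ≈ 600 is over half its value,
  so the ratio vector varies across replications even though the
  coefficient estimates themselves are unbiased (verified by the coverage
  tests).
* Conditional fits use the exact conditional likelihood; for very large
  strata this is slower than the approximations, and an unconditional fit
  with stratum indicators is a reasonable fallback.
* The per-SNP AUC definition is a reconstruction (see above); absolute AUC
  values depend on it, though metric-count selection barely does.

## Problem sizes used by the test suite

The suite exercises the pipeline at 120-2000 SNPs with the default stage
sizes (55/39 and 196/423), 50-seed selection replicates, 200-seed coverage
replicates, and exhaustive HWE enumeration to totals of 200 — sizes at
which every property is informative while the whole suite stays fast.
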