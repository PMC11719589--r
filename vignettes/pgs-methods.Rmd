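---
title: "Methods: weighted polygenic scores for asthma drug-pathway variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted polygenic scores for asthma drug-pathway variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models, the tunable parameters and their defaults, what the simulator does
and does not emulate, the numerical choices, and the known limitations. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The analysis

The package targets a case-control design: a fixed panel of 26 biallelic
SNPs in genes involved in the metabolism of the major anti-asthmatic drug
classes (glucocorticosteroids, beta-2-agonists, antihistamines,
antileukotrienes) or implicated in treatment response by GWAS, genotyped in
children with asthma and non-atopic controls. The default panel
(`default_panel()`) carries each SNP's counted allele, other allele and a
reference control-group MAF; the default group sizes are 378 cases and 504
controls, with 174 cases labelled moderate-to-severe.

The pipeline has five stages.

1. **QC** (`qc_report`, `prune_by_ld`): MAF, call rate, and an exact
   Hardy–Weinberg test per SNP; greedy LD pruning that visits SNPs by
   ascending association p-value and drops any SNP with dosage r² above a
   threshold (default 0.2) against an already-kept SNP.
2. **Association** (`fit_logistic_logadditive`, `assoc_scan`): per-SNP
   logistic regression under the log-additive model
   logit P(case) = α + β·g, g ∈ {0,1,2} copies of the counted allele.
   β is the log-odds per allele copy; the Wald p-value is the two-sided
   normal tail of β̂/SE. No covariates are fitted by default: the design the
   package emulates matched cases and controls on sex, age and ethnicity
   rather than adjusting for them.
3. **Weights** (`build_weight_set`): each SNP's risk allele is the allele
   with positive in-sample β̂ (ties at β = 0 keep the counted allele with
   weight 0). Weights are |β|, taken either from the in-sample scan
   (`local`) or from external GWAS summary statistics
   (`gwas_corrected`). External effects are sign-aligned to the counted
   allele by literal allele comparison — no strand-flip inference, because
   silently guessing strand for A/T and C/G SNPs corrupts weights. When an
   overlapping cohort's per-SNP effects are supplied, the external β is
   corrected by inverting the fixed-effect inverse-variance pooling
   formula (`remove_study_from_meta`): the leave-one-out estimate removes
   exactly the overlapping study's precision-weighted contribution. Panel
   SNPs absent from the summary statistics borrow an LD proxy's β,
   unmodified (no r²-attenuation), with provenance recorded as
   `proxy:<rsid>`.
4. **Scoring** (`compute_pgs`, `score_association`): the raw score is the
   weighted sum of risk-allele dosages. The score–disease odds ratio is
   estimated by logistic regression on the standardized score and reported
   per SD of the score in the analysed stratum; the per-SD unit is a
   reporting convention (echoed in the output's `scale` column), chosen
   because an unstandardized "per score unit" OR is not comparable across
   weight sets.
5. **ROC** (`roc_auc`, `auc_ci`, `operating_point`): AUC as the
   Mann–Whitney probability with tied pairs counted ½ (computed from
   midranks, which equals the brute-force pairwise statistic exactly);
   DeLong placement-value CI by default, stratified percentile bootstrap as
   a cross-check; Youden-optimal operating point with ties broken toward
   the lower threshold (higher sensitivity).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `ld_prune` | 0.2 | max pairwise dosage r² among retained SNPs |
| `hwe_alpha` | 0.05 | HWE flagging level (controls-only by default) |
| `exclude_hwe_failures` | `FALSE` | flag, do not drop (see below) |
| `proxy_r2` | 0.8 | minimum LD for an admissible proxy |
| `missing_policy` | `mean_impute` | missing risk dosage ← 2·(control risk-allele frequency) |
| `ci_method` | `delong` | AUC confidence interval |
| `severity_fraction` | 174/378 | fraction of cases moderate-to-severe |

Choices worth explaining:

* **HWE failures are flagged, not excluded, by default.** The simulator
  satisfies HWE by construction, so excluding at α = 0.05 would randomly
  drop about 5% of panel SNPs and silently change the 26-SNP design; the
  study design the package emulates likewise found no deviations and kept
  the full panel. Exclusion is available via `exclude_hwe_failures`.
* **`proxy_r2 = 0.8`.** Proxies are meant to be strong LD stand-ins; the
  threshold is configurable down to permissive values. The shipped proxy
  map (`default_proxy_map()`) carries `r2 = NA` because the original LD
  lookups are external and not re-derivable here: `NA` is accepted as
  user-asserted admissibility with a message, while numeric values are
  enforced against the threshold.
* **Controls define the imputation frequency** in `mean_impute`, keeping
  the imputed contribution independent of case status.
* **Table-level discrepancy in control counts.** The emulated study reports
  504 controls in its design section but 542 in its results table; the
  simulator parameterizes `n_controls` and defaults to 504.

## The simulator

`simulate_case_control()` draws, per individual, two independent haplotypes
per SNP (Bernoulli at the panel frequency), so genotypes are in
Hardy–Weinberg equilibrium by construction. Disease status is Bernoulli
with logit P(case) = intercept + Σ effectⱼ·gⱼ, and individuals are
accumulated by rejection until the configured case and control counts are
reached — mirroring case-control ascertainment with fixed group sizes. The
intercept is not identified by case-control data, so its default merely
makes rejection sampling efficient; effect sizes default to zero (a global
null), under which the contrast between in-sample and replicate weighting
isolates overfitting. Optional LD pairs are generated at the haplotype
level: the proxy haplotype copies the index haplotype with a mixing
probability solved so the population haplotype r² equals the target (exact
when the pair shares an allele frequency; with unequal frequencies the
realized proxy frequency shifts toward the index's, a documented
consequence of the copying model). A configured `missing_rate` masks calls
uniformly at random.

What the simulator does **not** emulate — and therefore what passing tests
do not establish about real data: population stratification and admixture
(the emulated sample spans several ethnicities), relatedness, genotyping
batch or chemistry artefacts, informative missingness, genome-wide LD
beyond configured pairs, covariate effects (age, sex), and
gene–environment interaction. Tests on simulated data validate the
*computations*, not the epidemiology.

## Numerical choices

* Logistic fits use `stats::glm` (IRLS, deviance tolerance 1e-12, ≤ 50
  iterations) followed by a three-step Newton polish on the observed
  information, putting the MLE and its SE at machine precision — required
  for exact agreement with closed-form 2×2 log-odds-ratios. Non-convergence
  and quasi-complete separation are flagged (`converged = FALSE`, `NA`
  statistics), never returned as silent numbers.
* The HWE exact test enumerates all heterozygote counts compatible with the
  observed minor-allele count on the log scale (stable for n in the
  thousands); the p-value sums configurations with probability at most the
  observed one, with a 1 + 1e-10 relative guard against ties lost to
  floating point.
* AUC via midranks is exact (half-integer arithmetic); the DeLong variance
  uses rank-computed placement values, O(n log n). Degenerate separation
  (AUC 0 or 1 with zero variance) collapses the CI to a point with a
  warning.
* Reported p-values are clamped to the smallest positive double so p ∈
  (0, 1] holds even at extreme z.
* All result TSVs format numerics to 8 significant digits via a fixed
  `sprintf` path, making reruns byte-identical; the run manifest contains
  no timestamps for the same reason.
* Leave-one-study-out meta-inversion requires the removed study's precision
  to be strictly below the pooled precision; anything else is a hard error
  (the subtraction would be undefined or produce a negative variance).

## Problem sizes in the test suite

The suite validates sampling behaviour at sizes chosen to make the checks
sharp but quick: 500-replicate coverage of the per-SNP effect at the
default 378/504 design; 2,000 null replicates (n = 500) for Wald type-I
error; 200 paired null replicates of the full 26-SNP design for the
in-sample versus out-of-sample contrast; full enumeration of every HWE
table up to n = 50; 1,000 random study sets for the meta-inversion
identity; AUC convergence checks at n = 20,000.

## Known limitations

* Only biallelic diploid GT calls are read from VCF; no dosage (DS) or
  imputed-probability fields, no BGEN/PGEN, no liftover.
* The regression offers no covariate adjustment path and no
  Firth/penalized fallback for separation; separated SNPs drop out of the
  weight set with a warning.
* Proxy βs are used unmodified; no r²-based attenuation or reference-panel
  LD computation is attempted.
* The severity stratum is a label on cases, simulated independently of
  genotype; real severity is unlikely to be independent of genetic load.
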