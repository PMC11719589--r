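# drugpgs

Weighted polygenic scores (PGS) for case-control studies of childhood
asthma, built from a fixed 26-SNP panel of drug-pathway gene variants —
genes involved in the metabolism of glucocorticosteroids, beta-2-agonists,
antihistamines and antileukotriene drugs, or implicated in treatment
response by GWAS. The package is aimed at statistical geneticists who want
to construct such a score, estimate its association with disease, and
evaluate its discriminative ability, with every stage testable on
simulated genotypes when individual-level study data are not available.

## What it computes

For individual *i* with risk-allele dosages *g<sub>ij</sub>* ∈ {0, 1, 2}
and per-SNP weights *w<sub>j</sub>* ≥ 0,

&nbsp;&nbsp;&nbsp;&nbsp;PGS<sub>i</sub> = Σ<sub>j</sub> w<sub>j</sub> · g<sub>ij</sub>

Risk alleles are oriented by the sign of the per-SNP log-additive logistic
regression β̂ in the analysis sample (logit P(case) = α + β·g). Weights are
either the in-sample |β̂| ("local" design) or external GWAS summary-statistic
βs ("gwas_corrected" design). In the latter case, when one contributing
cohort of the external fixed-effect inverse-variance meta-analysis overlaps
the analysis sample, its contribution is removed algebraically by inverting
the pooling formula: with precisions W = 1/SE²<sub>meta</sub> and
w = 1/SE²<sub>removed</sub>,

&nbsp;&nbsp;&nbsp;&nbsp;β<sub>loo</sub> = (W·β<sub>meta</sub> − w·β<sub>removed</sub>) / (W − w),
&nbsp;&nbsp;SE<sub>loo</sub> = (W − w)<sup>−1/2</sup>

Panel SNPs absent from the summary statistics borrow the β of a
user-supplied LD proxy. Scores are assessed by logistic regression of case
status on the standardized score (odds ratio per SD, Wald 95% CI) and by
ROC analysis (Mann–Whitney AUC with ties counted ½, DeLong or bootstrap
CI, Youden operating point). Supporting stages: Hardy–Weinberg exact
tests, MAF and call-rate QC, greedy LD pruning at r² > 0.2, VCF and PLINK
`.raw` genotype input, and a haplotype-level case-control simulator.

## Worked example

Simulate the default study design — the 26-SNP panel at its reference
control-group MAFs, 378 cases and 504 controls with 174 moderate-to-severe
cases, all true effects zero — then build an in-sample weighted score:

```r
library(drugpgs)
cfg   <- sim_config(seed = 26)        # default study design, global null
ds    <- simulate_case_control(cfg)
#> genotype_dataset: 882 individuals x 26 SNPs (378 cases, 504 controls)
assoc <- assoc_scan(ds)
ws    <- build_weight_set(ds$panel, assoc, mode = "local")
pgs   <- compute_pgs(ds, ws)
score_association(pgs, ds)
#>     stratum or_per_sd   ci_low  ci_high            p n_cases n_controls  scale
#> 1 all_cases  1.425254 1.239409 1.638965 6.660703e-07     378        504 per_sd
roc_summary(pgs$raw_score, ds$phenotype)
#> AUC 0.5882 (95% CI [0.5501; 0.6264], delong)
#> youden threshold 3.286: sensitivity 0.339, specificity 0.806 (378 cases / 504 controls)
```

Every true effect here is zero, yet the in-sample weighted score "predicts"
disease (OR 1.43 per SD, AUC 0.59): with 26 weights estimated and evaluated
on the same 882 individuals, overfitting alone produces an apparently
significant score. Rebuilding the weights on an independent replicate
(`modes = "replicate"` in `run_pipeline()`) returns the AUC to ≈ 0.5 —
the contrast the pipeline is designed to make visible. `run_pipeline()`
executes all configured weighting-design × stratum cells from one
configuration and writes deterministic TSV outputs plus a run manifest;
`inst/cli/drugpgs.R` exposes the same stages as shell subcommands.

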