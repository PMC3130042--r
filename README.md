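# metapqtl

Protein-level inference from label-free LC-MS peptide data, and genetics on
top of it. `metapqtl` is for proteomics/genetics analysts who have a
peptide-level (isotope-group) quantitation matrix, a single-SNP genotype
per sample, and a binary clinical outcome, and who want to know: *which
proteins does the variant move, and do they mediate the variant's effect on
the outcome?*

The package implements three linked analyses:

1. **Metaprotein rollup.** For each protein with ≥ 2 identified peptides, a
   one-factor sparse factor model with a spike-and-slab loading prior

   *x*<sub>ij</sub> = μ<sub>j</sub> + ρ<sub>j</sub> λ<sub>j</sub> f<sub>i</sub> + ε<sub>ij</sub>,  ε<sub>ij</sub> ~ N(0, ψ<sub>j</sub>),
   f<sub>i</sub> ~ N(0,1), λ<sub>j</sub> ~ N(0,τ), ρ<sub>j</sub> ~ Bern(π<sub>j</sub>)

   is fitted by variational EM, with π<sub>j</sub> high (0.95) for the seed
   protein's own peptides and tiny (0.001) for all others. Discordant seed
   peptides drop out; co-expressed foreign or unidentified peptides are
   recruited. The standardized posterior factor score is the per-sample
   protein phenotype ("metaprotein score").
2. **pQTL scan.** Each score is regressed on the C-allele count (additive)
   or the 1{non-CC} indicator (recessive), adjusting for sex and race, with
   Bonferroni control across factors, QQ diagnostics, genotype-only R², and
   per-peptide follow-up tests for significant factors.
3. **Mediation.** Nested logistic fits of the outcome (mediator-only,
   genotype-only, joint), with likelihood-ratio p-values,
   profile-likelihood intervals, and a labelled bias-reduced (Firth)
   fallback under separation, yielding a verdict: `mediates`,
   `independent` (pleiotropy), or `ambiguous`.

A synthetic-data generator (`sim_config()`, `simulate_study()`) emulates
the target study design — 41 patients, Hardy-Weinberg genotypes at C-allele
frequency 0.707, 10 proteins × 5 peptides, a planted genotype→protein
effect — with full ground truth, so every stage is testable end to end
without any external data. Readers are included for the TSV interchange
formats and for MATLAB v5 workspace files (`read_mat_workspace()`).

## Worked example

```r
library(metapqtl)

sim <- simulate_study(sim_config(seed = 7))   # cohort + peptide table + truth
fit <- fit_metaproteins(sim$peptides)
fit
#> <metaprotein_fit> 10 factors (0 skipped), 41 samples

scan <- pqtl_scan(fit$scores, sim$cohort)
scan
#> <pqtl_scan> 10 tests (additive model), Bonferroni alpha 0.005, 1 significant
head(tidy(scan)[c("target_id", "beta", "se", "p_value", "r2_genotype", "significant")], 3)
#>   target_id  beta    se      p_value r2_genotype significant
#> 1 PROT01    1.17  0.161 0.0000000119      0.594  TRUE
#> 2 PROT04    0.514 0.249 0.0465            0.111  FALSE
#> 3 PROT05    0.471 0.240 0.0571            0.0877 FALSE

d <- dplyr::inner_join(fit$scores[c("sample_id", "PROT01")], sim$cohort,
                       by = "sample_id")
mediation_analysis(d, "outcome", mediator = "PROT01")
#> <mediation_result> mediator PROT01, n = 41, verdict: independent
#> # A tibble: 7 × 7
#>   model   predictor method odds_ratio conf.low conf.high    p_value
#> 1 m_only  PROT01    ml       3.04e+ 0 1.37e+ 0    8.29   0.00528
#> 2 g_only  non_CC    ml       6.21e-15 1.22e-18    0.0657 0.00000145
#> 3 g_only  non_CC    firth    1.63e- 2 6.91e-30    0.135  0.00000805
#> 4 joint_g non_CC    ml       1.90e-15 7.02e-31    0.0489 0.0000535
#> 5 joint_g non_CC    firth    7.15e- 3 1.91e-40    0.165  0.000373
#> 6 joint_m PROT01    ml       5.25e- 1 1.16e- 1    2.01   0.346
#> 7 joint_m PROT01    firth    5.94e- 1 1.66e- 1    1.72   0.202
```

Reading the output: the scan finds exactly the planted pQTL (factor
`PROT01`, 1.17 score units per C allele, genotype-only R² 0.59,
Bonferroni-significant). In the mediation table the genotype fit separates
(the ML odds ratio collapses and is flagged; the Firth row gives the
stabilized estimate 0.016), the mediator's marginal association (OR 3.04)
is fully attenuated in the joint model (p 0.35) while genotype stays
significant — verdict `independent`, i.e. pleiotropy, exactly how the data
were generated (`outcome_beta_protein = 0`).

`run_pipeline()` chains all stages and writes `scan.tsv`, `qq.tsv`,
`mediation.tsv`, a fit directory, and a text report;
`autoplot(scan)` draws the QQ plot, `autoplot(fit)` the coverage/signature
composition bars. A thin CLI wrapper lives at `inst/cli/metapqtl.R`
(`simulate`, `run`, `replicate`, `qq` subcommands).

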