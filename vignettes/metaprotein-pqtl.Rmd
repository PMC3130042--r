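---
title: "Metaprotein factor models and pQTL association: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaprotein factor models and pQTL association: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapqtl)
```

## The problem

Label-free LC-MS proteomics quantifies *isotope groups* — a peptide at one
charge state and retention-time cluster — not proteins. Rolling isotope
groups up to protein-level abundance is noisy: identifications can be wrong,
peptides are shared between homologous proteins, and post-translationally
modified peptides can follow their own expression trajectory. `metapqtl`
addresses this with a *metaprotein* model: for each protein with at least
two identified isotope groups, a latent factor is fitted that groups
peptides by co-expression across the cohort, preferentially — but not
exclusively — keeping the protein's own peptides. The per-sample factor
score is then used as the protein-level phenotype in a protein quantitative
trait locus (pQTL) scan against a single biallelic SNP, followed by a
nested-logistic mediation analysis of a binary treatment outcome.

The motivating application is serum proteomics in chronic hepatitis C,
where the rs12979860 C/T polymorphism near *IL28B* strongly predicts
response to pegIFN/RBV therapy: does genotype move any serum protein, and
if so, does that protein mediate the genotype–response association?

## The metaprotein factor model

For one seed protein, let $x_{ij}$ be the log2 intensity of isotope group
$j$ in sample $i$. The model is a one-factor sparse factor analysis with a
spike-and-slab prior on the loadings:

$$x_{ij} = \mu_j + \rho_j \lambda_j f_i + \varepsilon_{ij}, \qquad
\varepsilon_{ij} \sim N(0, \psi_j),$$

with $f_i \sim N(0,1)$, $\lambda_j \sim N(0,\tau)$ and
$\rho_j \sim \text{Bernoulli}(\pi_j)$. The prior inclusion probability
$\pi_j$ is `pi_seed` (default 0.95) for the seed protein's own identified
peptides and `pi_other` (default 0.001) for every other feature in the data
set — peptides identified to other proteins and unidentified peptides alike.
This single asymmetric prior produces all three behaviours the rollup
needs: a discordant seed peptide whose trajectory does not track the factor
is *excluded* (its posterior inclusion probability falls below the
membership threshold of 0.5), a foreign or unidentified peptide whose
trajectory does track the factor is *recruited*, and everything else is
left out.

### Fitting

The model is fitted by coordinate-ascent variational EM with the
factorization $q(f)\,q(\rho,\lambda)$:

* $q(f_i) = N(a_i, s_i)$ — closed-form Gaussian update;
* $q(\rho_j, \lambda_j)$ — the exact spike-and-slab conditional: posterior
  inclusion log-odds
  $\operatorname{logit}\pi_j + \tfrac12\log(v_j/\tau) + m_j^2/(2v_j)$
  with $(m_j, v_j)$ the Gaussian slab posterior;
* M-steps for $\mu_j$ and $\psi_j$.

Missing intensities are omitted from the likelihood (missing-at-random);
there is no imputation in the final fit. Each sweep increases an evidence
lower bound (ELBO), which is also the convergence criterion: iteration
stops when the ELBO change falls below `tol * (1 + |ELBO|)` or all
parameters move by less than `tol` (default `1e-6`). The parameter
criterion matters in the noiseless limit, where $\psi_j$ is pinned at its
floor ($10^{-10}$) and the ELBO drifts without the fit changing. The sweep
limit `max_iter` defaults to 2000: the coordinate updates converge
geometrically and low-noise data can need on the order of a thousand cheap
sweeps, so a larger ceiling buys reliability at negligible cost.

Initialization is deterministic — $f$ starts at the first principal
component of the mean-imputed seed-peptide submatrix and loadings at their
regression values — so a fit is reproducible without any Monte Carlo. The
`seed` hyperparameter is recorded with the fit for provenance but the
algorithm draws no random numbers.

### Identifiability and conventions

The likelihood is invariant to jointly flipping $(\lambda, f)$; scores are
reported with the sign chosen so the mean loading of seed members is
positive, i.e. a lower score means lower protein level. Scores are
standardized to mean 0, variance 1 per factor; downstream regressions are
invariant to this, but odds ratios per score unit are not, which is worth
remembering when comparing absolute effect sizes across analyses. Each
factor is fitted independently per seed protein (a feature may join several
metaproteins); a joint multi-factor model over all proteins would couple
the factors and is deliberately out of scope.

Two composition metrics summarize each factor: **coverage**, the percent of
the seed protein's identified isotope groups that made it into the factor,
and **signature**, the percent of factor members that come from the seed
protein.

### Sparsity-off sanity check

With `pi_seed` and `pi_other` both pushed toward 1 and complete data, the
model degenerates to plain one-factor analysis, and on homoskedastic data
the posterior-mean score reproduces the first principal component of the
candidate submatrix essentially exactly (|r| above 0.999 in the test
suite). This anchors the implementation against an independent oracle.

## The pQTL scan

Genotype enters as the count of C (responder) alleles. The additive test is
the linear regression `score ~ allele_count + sex + race` with a two-sided
t-test on the allele-count coefficient — the covariate-adjusted analogue of
the one-way ANOVA trend test. The recessive test replaces the count with
the indicator `1{genotype != CC}`, so negative coefficients (and odds
ratios below 1 downstream) always refer to the non-CC group. A genotype-as-
three-level F-test is available as `model = "categorical"` for users who
want the unconstrained ANOVA. Samples with a missing score are dropped
listwise and `n_used` is reported per test.

Variance explained is reported twice: the primary `r2_genotype` is the
marginal R² of the score on the genotype term alone, and `r2_partial` is
the partial R² given sex and race. The two differ little when covariates
are weak, but the marginal number is the one comparable across studies that
do not adjust.

The scan applies one test per factor and controls the family-wise error
rate by Bonferroni (`family_alpha / K`). QQ coordinates use mid-rank
uniform quantiles, `-log10((i - 0.5)/K)`; `autoplot()` on a scan draws the
diagnostic.

## Mediation by nested logistic models

Whether a significant factor *mediates* the genotype–outcome association is
assessed by the attenuation pattern across three logistic fits sharing one
sample: outcome on mediator, outcome on the recessive genotype indicator,
and outcome on both (each adjusted for sex and race). P-values are
likelihood-ratio tests of dropping the predictor and 95% intervals are
profile-likelihood, computed by direct inversion of the LRT with a root
finder. Wald intervals are emitted alongside, but at n ≈ 41 with odds
ratios as extreme as 0.03 the Wald approximation is unreliable — its
interval can straddle 1 while the LRT is clearly significant — so the
profile/LRT pair is the default reading.

Small cohorts with strong effects frequently produce (near-)separation. The
maximum-likelihood row is then flagged `converged = FALSE` and a
bias-reduced fit (Firth's Jeffreys-prior penalty, implemented in-package
with the same Newton and profiling machinery) is appended as a clearly
labelled second row — reported alongside, never silently substituted.

The verdict rule: **independent** (pleiotropy) when both marginal fits are
significant, the mediator's joint-model p ≥ 0.05 and the genotype's
joint-model p < 0.05; **mediates** when the attenuation falls on the
genotype instead; **ambiguous** otherwise. No formal natural-effect
decomposition is attempted — the deliverable is the nested-model
attenuation comparison.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions the pipeline is meant
for, at one tenth of the proteome scale: 41 patients; Hardy–Weinberg
genotypes with C-allele frequency 0.707 (so the CC genotype has expected
frequency 0.50); sex and race at the cohort margins (61% male, 78%
Caucasian); 10 proteins with 5 peptides each; loadings uniform on
[0.8, 1.2]; residual SD 0.5 on the log2 scale; 5% missing cells; 5% of
peptides promiscuously loading on one foreign factor; a genotype effect of
1.16 score units per C allele on protein 1; and an outcome model with odds
ratio 0.03 for the non-CC indicator and no direct protein effect — the
pleiotropy configuration. Peptide-level variance components are not
reported for the original study, so the noise defaults are plausible
values, not estimates.

All randomness derives from one integer seed, split deterministically into
purpose-specific streams (genotypes, covariates, scores, loadings,
membership, noise, masking), so changing the missing rate never perturbs
the genotypes — ablations stay paired.

What the generator does *not* emulate: retention-time drift, isotope
envelopes, intensity-dependent missingness (censoring), identification
errors beyond random promiscuity, and correlated residuals. Passing
recovery tests therefore demonstrate correctness of the algorithms under
the model's own assumptions, not robustness to every real-data pathology.

## Problem sizes and numerical choices in the checks

The test-suite and acceptance-script simulations use desk-scale sizes
chosen to give the relevant statistics conventional power: ground-truth
recovery at n = 41–50 with 10×5 features and residual SD 0.5; type-I error
over 1000 null cohorts at n = 41; family-wise error over 200 scans of 110
null factors; confidence-interval coverage over 200 replicates; and
mediation-verdict rates over 200 replicates at n = 160 with log-odds
effects of −2 (genotype, pleiotropy scenario) or +1 per score unit
(mediator, full-mediation scenario). The verdict scenarios use a larger n
than the motivating cohort deliberately: the verdict rule compares four
nested tests, and at n = 41 with near-separating effects its error rate is
dominated by small-sample artefacts rather than by the logic under test.
The PCA-equivalence check uses residual SD 0.2 because factor analysis and
PCA coincide only as noise becomes homogeneous and small; at higher noise
the two estimators legitimately differ.

Degenerate inputs are handled explicitly rather than by numerical luck:
constant responses return a null association (beta 0, p 1); constant
genotype terms, one-class outcomes, collinear designs, empty seeds and
all-excluded factors raise classed errors that the scan and pipeline
downgrade to skipped entries with warnings.

## Known limitations

* Exact replication of the original study's numbers requires its deposited
  MATLAB workspace; the reader (`read_mat_workspace()`) and the
  `replicate_tables()` layout are in place, and the acceptance checks
  against those numbers activate when the workspace file is placed under
  `inst/extdata/study/`.
* The factor model assumes missing-at-random intensities; LC-MS
  missingness is partly abundance-driven, which biases low-abundance
  loadings toward exclusion.
* One SNP at a time; genome-wide scans should loop externally.
* Whether the original analysis standardized scores before the logistic
  fits is unknown; odds ratios per score unit depend on that choice even
  though p-values largely do not.
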