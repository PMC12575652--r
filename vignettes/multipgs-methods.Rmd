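---
title: "Composite multi-PRS risk prediction: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite multi-PRS risk prediction: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(multipgs)
```

## The problem

A disease-specific polygenic risk score (PRS) summarizes a person's common
genetic liability for one trait as a weighted sum of effect-allele dosages.
Because complex traits share genetic architecture (pleiotropy), published
PRSs for *other* traits — metabolic, anthropometric, even behavioral —
carry information about colorectal-cancer (CRC) risk that a CRC-specific
score may miss, whether because its discovery GWAS lacked power at some
loci or because shrinkage-based weight estimation over-penalized them.

`multipgs` implements a multiple-polygenic-score (MPS) workflow that turns
this idea into a tested pipeline:

1. **Candidate filtering.** A catalog of published scoring files is pushed
   through a four-stage exclusion cascade (no overlapping variants; more
   than 20% of scoring variants unavailable in the genotype data; traits
   that *are* CRC, colon or rectal cancer; broader gastrointestinal and
   rectal/anal-cancer traits whose case sets contain many CRC cases).
   Scores for CRC precursor lesions — benign colon neoplasms, rectal
   polyps — are deliberately retained: they predict precursors, not the
   disease, and turn out to carry much of the MPS signal.
2. **Selection.** The surviving standardized PRSs enter a penalized
   logistic regression with elastic-net penalty on the PRS block only; age,
   sex and genotyping platform stay unpenalized. The mixing parameter
   $\alpha$ and penalty strength $\lambda$ are tuned by 10-fold
   cross-validation on the *confounder-adjusted* AUC, the model is refitted
   on the full development data, and the composite MPS is the linear
   combination of the PRSs with nonzero refit coefficients, standardized to
   mean 0, SD 1.
3. **Risk models and validation.** On an independent evaluation cohort,
   split in half, six nested logistic models are fitted on the training
   half — CRC-KL200 (a sparse known-loci CRC score), CRC-LDpred (a
   genome-wide CRC score), their combination, and each of the three with
   the MPS added — and validated on the held-out half by confounder-
   adjusted AUC with bootstrap standard errors and three *paired*
   comparisons (model 4 − 1, 5 − 2, 6 − 3) tested by a bootstrap z-test.

## The confounder-adjusted AUC

Age and sex predict CRC strongly; an AUC computed on a raw risk score would
credit the score for discrimination that really belongs to them. The
adjusted estimator reweights cases so their confounder distribution matches
the controls':

$$\widehat{AUC}_w \;=\;
\frac{\sum_{i \in \text{cases}} \sum_{j \in \text{controls}}
      w_i\,\big(\mathbf 1[s_i > s_j] + \tfrac12 \mathbf 1[s_i = s_j]\big)}
     {n_0 \sum_i w_i},
\qquad
w_i \;=\; \frac{P(\text{stratum}_i \mid \text{control})}
               {P(\text{stratum}_i \mid \text{case})}.$$

Two weight engines are provided. `strata` (default) computes the exact
post-stratification ratio over the cells of the categorical confounder
cross-classification (age binned by decade via `bin_age()`); it is exactly
testable against brute-force enumeration and reproduces the defining
property that the weighted case distribution equals the control
distribution cell by cell. `model` fits a main-effects logistic regression
of the label on the confounders and uses inverse-odds weights
$w_i \propto (1-\hat p_i)/\hat p_i$, which accommodates continuous
confounders. Cases falling in strata with no controls receive weight zero
and are counted in a warning. Ties contribute 1/2 (the usual Mann–Whitney
convention), and the sum is evaluated by a sort-and-count algorithm that is
contract-equal to the $O(n_1 n_0)$ double loop to $10^{-12}$.

Uncertainty comes from the nonparametric bootstrap: individuals are
resampled with replacement (unstratified; replicates that lose a class are
redrawn and counted), the adjusted AUC is recomputed per replicate, the SE
is the replicate SD and the 95% CI the 2.5/97.5 percentiles. For model
comparisons the *same* resample indices are applied to both models, so the
correlation between the two AUCs is respected; the test statistic is
$z = \Delta\widehat{AUC} / SE_{boot}$ with a two-sided normal p-value. A
percentile CI (rather than normal-approximation) was chosen because it is
transformation-respecting near the AUC's boundary; the z-test itself uses
the bootstrap SE, matching the difference-then-z construction of the
validation step.

## Penalized selection

The selection objective is

$$\frac1n \sum_i -\ell_i(\beta)
  + \lambda \sum_{j \in \text{PRS}}
    \Big[\alpha |\beta_j| + \tfrac{1-\alpha}{2}\beta_j^2\Big],$$

with intercept and covariates unpenalized. Fitting delegates to glmnet's
coordinate descent; because glmnet rescales penalty factors to sum to the
number of variables, the wrapper shrinks the lambda it passes down by
$K/(K+c)$ ($K$ penalized PRSs, $c$ covariates) so that `lambda` in this
package *is* the nominal per-PRS penalty of the objective above. Tests pin
this correspondence against independent optimizers: at $\lambda = 0$
against a BFGS maximum-likelihood fit, at $\lambda = 10^6$ against the
covariate-only model, and at a ridge point against direct minimization of
the explicit objective.

Cross-validation folds are label-stratified by a seeded shuffle. The
held-out fold is scored with the **PRS-only** linear predictor
$\sum_j \beta_j \text{PRS}_{ij}$: the covariates' predictive contribution is
deliberately excluded from the score because the adjusted AUC exists
precisely to measure the PRSs' own discrimination — putting age and sex
back into the score would re-import them. The grid default is
$\alpha \in \{0, 0.25, 0.5, 0.75, 1\}$ (ridge, elastic net and lasso as
regions of one grid) and 50 log-spaced $\lambda$ values from the
data-derived $\lambda_{max}$ (the smallest penalty zeroing every PRS at
$\alpha = 1$) down to $10^{-4}\lambda_{max}$. Exact ties in mean CV AUC
break toward larger $\lambda$, then larger $\alpha$ — the sparser model.

A known behavior, documented rather than hidden: tuning by the CV
*maximum* overselects. Cross-validation folds share the cohort's chance
sample correlations between uninformative PRSs and the outcome, so the CV
curve is flat near its maximum and the outright argmax is decided by fold
noise — in the simulated pleiotropy scenario the informative trait PRSs
are selected essentially always, but unrelated traits also enter a noticeable
minority of refits, and their coefficients do not transfer to new
cohorts. `cv_select(rule = "max")` keeps the plain argmax (with exact ties
broken toward larger $\lambda$, then larger $\alpha$); the pipeline
defaults to `rule = "1se"`, the familiar one-SE parsimony rule: among grid
points whose mean CV AUC is within one standard error of the best, take
the one with the fewest nonzero PRS coefficients (ties again toward larger
$\lambda$, then $\alpha$). Under the one-SE rule the simulated selection
concentrates on the pleiotropic traits.
The test suite asserts strongly preferential selection for the plain rule
and sparsity-within-one-SE for the parsimony rule.

## Risk models

The six models are maximum-likelihood logistic regressions with age
(centered) and sex (male = 1) as covariates; per predictor the package
reports the odds ratio per 1-SD increment, the Wald 95% CI
$\exp(\hat\beta \pm 1.96\,SE)$ and the two-sided Wald p-value. The primary
endpoint is advanced neoplasia (CRC or advanced adenoma vs everyone else);
the secondary `crc_only` endpoint uses CRC cases against controls with
advanced-adenoma records excluded. Rank-deficient designs are refused with
the collinear columns named. Sex-stratified suites refit the six models per
sex with age as the only covariate. All score standardizations on the
evaluation cohort use training-split moments only, so no validation
information leaks into step 2; the fold/cohort moments are recorded on
every score object for exactly this reuse.

## The synthetic cohort generator

The simulator emulates the statistical structure the pipeline assumes
without any real genotype data:

* **Genotypes**: MAFs uniform on `maf_range` (default 0.05–0.5), dosages
  i.i.d. Binomial(2, MAF) — Hardy–Weinberg equilibrium and *linkage
  equilibrium*. No LD is simulated: LD matters for building PRSs, not for
  the contracts of scoring, selection or validation, and its absence keeps
  every oracle exact.
* **Liability**: $L = g + 0.5\,z(\text{age}) + 0.3\,\text{male} +
  \varepsilon$, with the genetic value $g$ scaled to variance
  `h2_liability` (default 0.25, in the range of SNP-heritability estimates
  for CRC) and $\varepsilon \sim N(0, 1-h^2)$. Age is N(65, 10²) truncated
  to [40, 90]; both thresholds are theoretical normal quantiles of $L$:
  above the 0.95 quantile → CRC, between 0.90 and 0.95 → advanced adenoma
  (modeled as a lower band of the *same* liability axis, consistent with
  treating adenomas as precursors on one risk continuum), else control.
* **Pleiotropy**: each secondary trait's causal set (10% of variants by
  default) overlaps the CRC causal set by `shared_causal_fraction`
  (defaults: 3 of 10 traits at 0.5, the rest at 0), reusing the CRC weights
  on shared variants and topping up with its own, rescaled so every trait's
  genetic variance is `h2_liability`.
* **Published weights**: additive Gaussian noise with SD
  `weight_noise_sd` × (causal-weight SD), default 1 — i.e. per-variant
  noise as large as the signal, a deliberately pessimistic stand-in for
  weights estimated from moderate GWAS. A noise-free variant
  (`crc_noiseless`) represents a well-estimated genome-wide score.
* **Scoring files**: written in the PGS-Catalog dialect with controlled
  missingness injected by relocating a fraction of variants outside the
  simulated region, so the exclusion cascade has something real to do.
* **Study designs**: the development dataset is sampled as a *case-control
  study* (`simulate_case_control`, advanced-neoplasia cases enriched to
  48%, the balance of CRC GWAS consortia), while the evaluation cohort
  keeps its population structure (~10% advanced neoplasia) — the two-stage
  design the workflow assumes. All rejection-sampling chunks share one MAF
  draw so case enrichment never induces artificial frequency structure.

What passing tests on these cohorts do *not* show: robustness to LD
(overlapping scores built on correlated variants), strand ambiguity (the
simulator emits unambiguous A/G–C/T pairs; an ambiguous-variant drop flag
exists but is exercised only structurally), genome-build mismatches,
ancestry structure, or realistic GWAS estimation error. The pipeline's
contracts are orientation- and missingness-aware, but claims about real
cohorts remain claims about the contracts, not about those complications.

## Numerical choices and degenerate inputs

* Sample SD (n−1) throughout; standardization moments always recorded and
  reapplied rather than recomputed.
* Missing dosages at a matched variant are imputed with that variant's
  sample-mean stored dosage (the standard scoring convention; preserves
  score means and vanishes when nothing is missing).
* "More than 20% missing" is strict: overlap exactly 0.80 is kept.
* Variant identity is `chromosome:position:sorted-allele-pair`, so both
  orientations of a record match; rsIDs are only a fallback when positions
  are absent. Allele pairs that disagree at a shared position are
  unmatched, never guessed.
* glmnet convergence threshold 1e-12 with a warm-start lambda ramp, so the
  oracle comparisons at 1e-5/1e-6 tolerances are meaningful.
* All scores identical → AUC 0.5 by the tie convention, not an error; a
  degenerate bootstrap (zero SE, nonzero delta) reports p = 0 with a
  warning; an empty composite (no PRS selected) yields a zero MPS column
  and comparisons that degenerate to delta 0, p 1.
* Every stochastic step (simulation stages, fold assignment, splits,
  bootstraps) takes an explicit seed and is bit-reproducible; simulator
  stage seeds derive from the config seed by fixed offsets so cohorts and
  weights can be regenerated independently.

## Problem sizes used by the packaged analyses and tests

The analysis scripts and the heavier tests run at the default study size
(two cohorts of 10,000 individuals × 1,000 variants, 10 candidate traits);
the selection-recovery and end-to-end checks repeat that 20× under
different seeds. Unit oracles run on deliberately tiny instances (tens of
individuals) where brute-force enumeration is exact. The bootstrap
calibration studies use n = 2,000 with 200 bootstrap replicates and 500
simulation repeats for the type-I error of the paired z-test, and n = 300
with 200 replicates and 200 repeats for CI coverage.

## Open design points resolved here

* The 20%-missingness rule is applied against a single variant index;
  reproducing a multi-dataset rule is done by intersecting indexes before
  the call (the stricter reading).
* Evaluation-cohort scores are standardized with the evaluation cohort's
  *training-split* moments, not the development cohort's: each cohort is
  standardized internally, and within the evaluation cohort the
  training→validation transfer guards against leakage.
* CV folds are label-stratified (guarantees both classes in every fold
  whenever each class has at least `n_folds` members).
* Validation AUCs score the PRS part of each model's linear predictor;
  age and sex act through the adjusted-AUC reweighting.
* Ambiguous-strand variants (A/T, C/G) are scored as matched by default;
  `match_variants(..., drop_ambiguous = TRUE)` removes them. The simulated
  data carry no strand issues, so the default is safe there.
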