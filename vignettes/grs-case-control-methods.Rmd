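---
title: "Combined-variant genetic risk scores for case-control panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined-variant genetic risk scores for case-control panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grspanel)
```

# The problem

Recurrent pregnancy loss (RPL) — two or more consecutive first-trimester
miscarriages — is a multifactorial condition in which individual genetic
variants contribute small per-allele risks that are hard to establish one at
a time in modest samples. A combined genetic risk score (GRS) aggregates a
curated panel of candidate variants spanning the biological pathways of
pregnancy maintenance (blood coagulation, hormonal regulation, placental
function, folate metabolism, inflammatory response) into one per-person
covariate, which can then be tested for association with case status and
evaluated as a classifier.

`grspanel` implements this analysis end to end for a 13-variant candidate
panel (pruned to 12 for scoring) together with a cohort simulator that
reproduces the statistical structure the analysis assumes, so that the
estimators can be validated by parameter recovery and calibration studies.

# Models

## Per-variant association: the log-additive model

For variant $j$ with effect-allele dosage $d_{ij} \in \{0, 1, 2\}$ and case
indicator $y_i$, the single-variant model is ordinary logistic regression

$$\operatorname{logit} P(y_i = 1) = \alpha_j + \beta_j d_{ij},$$

the log-additive coding standard in genome-wide association studies: each
additional effect-allele copy multiplies the odds by $e^{\beta_j}$. Fits are
maximum likelihood (IRLS, deviance tolerance $10^{-8}$, at most 100
iterations) on the complete cases for that variant — genotyping here is
enrolment-dependent, so the genotyped subsample legitimately differs across
variants, and no imputation is attempted (candidate-gene data carry no
genome-wide LD information to impute from). Inference is Wald throughout:
$\operatorname{se}(\hat\beta_j)$ from the observed information,
$\text{CI} = \exp(\hat\beta_j \pm z_{0.975}\,\operatorname{se})$, two-sided
normal p-values, reported nominally (no multiple-testing correction — the
table is descriptive, and downstream conclusions rest on the combined
score). The very wide intervals that sparse cells produce (a handful of
rare-allele carriers) are characteristic of Wald inference and are kept as
such; fits with separated or constant dosage are flagged in a `status`
column rather than reported as silently huge numbers.

## The score and its missingness correction

With weights $w_j$ (log odds ratios), the raw score of person $i$ is
$s_i = \sum_{j \in G_i} w_j d_{ij}$, summed over the variants $G_i$
genotyped in that person; a missing genotype contributes nothing and
decrements the count $m_i = |G_i|$. Because people genotyped at fewer
variants would otherwise have systematically smaller scores, the score is
rescaled by the genotyped fraction:

$$\tilde s_i = s_i \cdot \frac{M}{m_i},$$

with $M$ the scoring-panel size (12 here — the panel after LD pruning, not
the 13-variant candidate set). This is exact algebra, not an estimate: the
package computes it as written, keeps $\tilde s_i = s_i$ bit-identical when
$m_i = M$, and refuses to score a person with $m_i = 0$ (such samples go to
an exclusion report). The GRS–phenotype association is then a logistic fit
of $y$ on $\tilde s$ as a single continuous covariate, so the reported OR is
per unit of corrected score. The score is deliberately not standardised by
default — a `standardize` switch exposes per-SD effects for sensitivity
checks, since per-unit and per-SD ORs are easy to conflate across studies.

## Weighting schemes

Three schemes are built by `build_weight_scheme()`:

* **published-mixed** (headline): $w_j = \log(\text{published OR}_j)$ for
  the five variants whose prior RPL estimate is ethnically transferable
  (F2, F5, ESR1, ACE, MTHFR); in-study estimates for the seven others —
  four (F7, GP1A, ADRB2, IL8) because no prior RPL association exists, and
  three (ENOS, IL6, IL10) because the published estimates come from
  ethnically discordant studies. The source rule is data, not code: it is a
  `weight_source` column in the panel table, so user panels can encode
  their own rule.
* **study**: all twelve weights from the in-study per-variant fits
  (sensitivity check on the external weights).
* **unit**: all weights one — an unweighted risk-allele count; for a fully
  genotyped person the corrected score is an integer in $[0, 24]$.

Non-SNP panel members (the ACE indel, the ENOS intron-4 VNTR, the IL6 14718
repeat) are coded as ordinary biallelic dosages of their effect allele: each
has a defined effect/other allele pair and behaves exactly like a SNP in
every formula. One panel inconsistency is worth noting: the panel table
lists the F5 variant with A/G allele labels while its literature entry uses
T/C (a strand/naming discrepancy for rs6025); the fixture follows the
genotype-table labels. Similarly, the published ESR1 and ACE ORs enter the
published-mixed weights as printed even though the in-study estimates for
those variants point the other way — weighting choices are made before
looking at the data they weight.

## ROC evaluation

The score is assessed as a classifier by the empirical ROC curve with the
risk-score convention fixed: predict "case" when score $\ge$ threshold, one
operating point per distinct score value plus $\pm\infty$ sentinels. The
AUC is the trapezoidal area, which for the empirical curve equals the
Mann–Whitney pair statistic (probability a random case outscores a random
control, ties counting one half) — the package tests this identity against
brute-force pair counting. The AUC interval is DeLong's placement-value
variance with a normal approximation truncated to $[0,1]$ (the default of
the field's standard ROC software; a stratified percentile bootstrap is
available behind the `ci` argument). The "best discriminating point" is the
Youden maximiser of sensitivity + specificity − 1, with deterministic tie
breaks: higher sensitivity first, then lower threshold. Perfectly separated
data give a degenerate (zero-variance) DeLong interval, which collapses to
the point estimate with a warning rather than failing.

# The simulator

The generator exists to produce cohorts with exactly the structure the
analysis assumes, with known truth:

* **frequency-matched mode** draws each dosage as
  $\text{Binomial}(2, p_{g j})$ — Hardy–Weinberg proportions at the
  group-specific effect-allele frequency. The packaged template
  (`replik_template_config()`) is preloaded with the printed structure of
  the REPLIK study: 114 cases / 106 controls, the twelve per-group EAFs,
  and per-variant genotyped counts ranging from 75/46 (rs6046) to the full
  114/106 (rs1800896, rs2227306).
* **logistic-liability mode** draws genotypes at population frequencies and
  assigns case status by $P(y=1) = \operatorname{logit}^{-1}(\alpha +
  \sum_j \beta_j d_{ij})$ with user-specified true effects, accumulating
  individuals by rejection sampling until the case and control quotas are
  met (attempt cap: 100× the target size). Case-control sampling biases
  only the intercept, so fitted slopes are directly comparable with the
  truth — the basis of the recovery study.
* **missingness injection** removes genotypes per variant and per phenotype
  group, uniformly at random, until exactly the configured number of
  genotyped individuals remains (already-missing cells count toward the
  quota). This is missing-completely-at-random given phenotype: the real
  pattern is enrolment- and reagent-driven, which is plausibly independent
  of genotype, making MCAR-within-group the weakest sufficient assumption.
  A pattern that would leave any sample with no genotyped variant is
  rejected.

All generation is reproducible: a config seed fully determines the cohort
(the missingness draw uses a sub-stream derived from the same seed), and the
generator restores the caller's RNG state.

What the simulator does *not* emulate — and hence what passing simulation
tests cannot certify about real data: linkage disequilibrium between panel
variants (the scoring panel is LD-pruned and spans distinct loci, so
independence matches the analysis assumption, but real residual LD would
correlate score components); covariates such as maternal age (the models
here are unadjusted, as in the source analysis); genotyping error; and any
missingness mechanism correlated with genotype or outcome beyond the
per-group quotas.

# Validation studies and problem sizes

Three simulation studies back the estimators; they live in the test suite
and in `analysis/05_calibration_studies.R`, with sizes chosen to bound
Monte-Carlo error usefully at interactive runtimes:

* **parameter recovery** — 200 liability-mode replicates at 114/106 with a
  known slope of 0.4 on the corrected-score scale: mean recovered slope
  within Monte-Carlo error of the truth, Wald 95% CI coverage within
  0.95 ± 0.03.
* **null calibration** — 2000 frequency-matched replicates with identical
  group frequencies: per-variant Wald rejection at $\alpha = 0.05$ within
  0.05 ± 0.01, mean unit-score AUC within 0.50 ± 0.01.
* **interval coverage for the AUC** — 500 replicates at a known population
  AUC computed exactly from the two binomial genotype distributions by pair
  probability: DeLong coverage within 0.95 ± 0.03.

The estimator-versus-oracle checks are exhaustive rather than stochastic:
grid search of the binomial log-likelihood for the logistic MLE (coarse
0.05 grid, refined to 5×10⁻⁴) on small instances, pair counting for the
AUC, threshold enumeration for the ROC points, and the field-standard ROC
package as an independent cross-check of AUC and DeLong bounds.

# Degenerate inputs and numerical choices

* Separation (including the quasi-separation that sparse rare-allele
  tables produce) is detected via the fitted-probability diagnostic and a
  standard-error guard, and flagged in `status`; estimates are not clamped.
  Note the divergence of the MLE under quasi-separation is a property of
  the data, not a numerical failure: with a variant at EAF ~0.02 and 46
  genotyped controls, zero-carrier control groups are expected in a
  substantial fraction of simulated cohorts.
* Constant dosage or single-class phenotype gives `NA` estimates with an
  explanatory status instead of an error inside table-producing loops; a
  variant that fails does not abort the rest of its table.
* All thresholds and tolerances are fixed: glm deviance tolerance $10^{-8}$,
  max 100 iterations; Youden ties resolved toward sensitivity then lower
  threshold; DeLong truncation to $[0,1]$.
* Output tables are TSV, UTF-8, `NA` for missing, full-precision numbers;
  every table the pipeline writes is re-readable by the package's own
  readers, and a fixed-seed pipeline run is byte-identical across
  executions.

# Known limitations

* Weights mix externally published and internally estimated effects; the
  in-study weights are estimated on the same cohort they score, which
  overfits the study-scheme GRS slightly (visible as its higher in-sample
  AUC). The published-mixed scheme is the headline precisely to limit this.
* The missingness correction rescales means but inflates the variance of
  scores for sparsely genotyped individuals; no shrinkage is applied.
* No LD-aware weighting or genome-wide scoring: this is a candidate-panel
  method, and the single high-LD pair in the default panel is resolved by
  rule-based exclusion (flag in the panel table), not by LD computation
  from reference data.

# Session

```{r session, eval = FALSE}
sessionInfo()
```
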