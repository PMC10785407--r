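---
title: "Two-stage SNP association, genetic risk scores and CART interaction analysis for noise-induced hearing loss"
author: "grscart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage SNP association, GRS and CART for NIHL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grscart)
```

## The scientific problem

Occupational noise-induced hearing loss (NIHL) is a polygenic trait:
workers exposed to the same noise dose differ widely in how much hearing
they lose, and individual candidate SNPs carry small effects (odds
ratios mostly below 2).  The standard study design in this field is a
two-stage candidate-SNP case-control study: a small screening cohort
genotyped on a wide panel proposes candidates, and an independent
replication cohort confirms them.  The replicated SNPs then feed two
multigenic analyses:

* an **unweighted genetic risk score** (GRS) — the per-subject sum of
  risk-genotype codes (0 = homozygous non-risk, 1 = heterozygous, 2 =
  homozygous risk) — with binned dose–response estimation; and
* a **classification tree** (CART) over genotypes and environmental
  exposures, whose terminal nodes define subject strata with their own
  odds ratios against the lowest-risk stratum, exposing gene–gene and
  gene–environment interactions that single-SNP models miss.

`grscart` implements this whole workflow as a tested, reusable pipeline,
plus a synthetic cohort generator so every stage can be exercised and
calibrated without access to individual-level study data.

## Case definition and exposure metrics

Case status is audiometric.  From per-ear pure-tone thresholds (dB HL):

* **BHFTA**, the binaural high-frequency threshold average, is the mean
  of the 3000/4000/6000 Hz thresholds over both ears.
* **MTWV**, the monaural weighted threshold value, is
  $0.9 \cdot \overline{T_{500,1000,2000}} + 0.1 \cdot T_{4000}$ for one
  ear.

A subject is a *case* when BHFTA $\ge$ 40 dB **and** MTWV $\ge$ 26 dB, a
*control* when both fall below their cutoffs, and *indeterminate*
otherwise.  The monaural criterion is evaluated on the **worse** ear by
default (`ear = "worse"` in `classifyHearingStatus()`): a monaural
diagnostic criterion is met as soon as one ear meets it, which is the
conservative reading; the lenient better-ear reading is available.

Cumulative noise exposure combines level and duration on the
equal-energy principle:

$$\mathrm{CNE} = \mathrm{SPL} + 10\log_{10}(\text{years}),$$

in dB(A)·years, where SPL is the 8-h equivalent A-weighted level
($L_{Aeq,8h}$).  Note that a frequently printed variant of this formula,
"$10\times\log(10^{SPL}\cdot years)$", is not evaluable for dB-scale SPL
(it would exponentiate 85); the form above is the standard equal-energy
expression, equals $10\log_{10}(10^{SPL/10}\cdot years)$, and reproduces
the magnitudes reported for such cohorts (~96 dB(A)·years at ~85 dB(A)
and ~12 years).

## The association stage

**QC.** Each SNP must have call rate $\ge$ 90% and must not deviate from
Hardy–Weinberg equilibrium in **controls** at $p < 0.01$ (Pearson 1-df
$\chi^2$ against $p^2, 2pq, q^2$).  Failing *either* criterion excludes
the SNP (`combine = "or"`); requiring both (`"and"`) is available but
would retain SNPs that are individually unusable.

**Genetic models.** Five dichotomizations of the genotype plus a dosage:
recessive (BB vs rest), dominant (AB/BB vs AA), super-dominant (AB vs
homozygotes), homozygote (BB vs AA, AB excluded), allele (per-allele
counting, two alleles per subject) and additive (dosage 0/1/2).  Calls
are always stored relative to the panel's declared wild allele; VCF
import flips homozygotes when REF is the panel's variant allele.  The
package fixes exposure = the variant-containing grouping; since
published tables sometimes print the reciprocal orientation, the
reciprocal OR is just `1/OR` with the CI reflected (a tested invariant).

**Estimation.** Crude odds ratios are the 2×2 cross-product with Woolf
(log-scale Wald) 95% intervals; a Haldane–Anscombe correction (+0.5 to
every cell) is applied, and flagged, only when a cell is zero.  Adjusted
odds ratios come from maximum-likelihood logistic regression
(`stats::glm.fit`, IRLS, tolerance $10^{-8}$, max 100 iterations) on the
model exposure plus covariates — by default age, years of noise
exposure, smoking and drinking.  The allele model cannot be
covariate-adjusted at the allele level, so its adjusted counterpart is
the subject-level additive dosage fit, flagged as such.  Perfect
separation is detected (|coef| > 15 or IRLS non-convergence) and
reported as a flag, never as an exception.  Wald p-values are used
throughout for consistency with the Woolf intervals.  No multiplicity
correction is applied by default: the two-stage design itself is the
replication-based guard against false positives.

**Two-stage selection.** Stage 1 keeps SNPs with adjusted $p < 0.10$
(significant or marginal) under at least one model; stage 2 keeps, of
those, SNPs with adjusted $p < 0.05$ under at least one model in the
independent replication cohort, recording which models drove selection.

## The GRS stage

The risk allele of each validated SNP is the allele whose **allele-model
crude OR exceeds 1 in the replication cohort** — the replication stage
is the study's final word on direction; ties break toward the variant
allele with a warning.  The GRS is the unweighted sum of risk-allele
counts over the validated SNPs; subjects missing any scored genotype are
excluded (a prorated score is available and flagged).  Subjects are
binned (default $\le 5, 6, 7, 8, 9, \ge 10$) with the lowest bin as
reference; per-bin ORs are Woolf cross-products against the reference,
the $\ge 6$ vs $< 6$ dichotomy is reported, and dose–response is tested
with the Cochran–Armitage trend test (`stats::prop.trend.test`) using
ordinal scores $0..k-1$ — the standard dose-response $\chi^2$ for binned
case-control data; open-ended bins have no defined midpoint, so ordinal
scores are the coherent choice.  A weighted GRS (per-allele log-OR
weights) is deliberately not provided.

## The CART stage

The tree is grown from scratch on the learning set (a stratified random
65% of subjects) by recursive binary partitioning:

* **Splitting** maximizes information gain — parent entropy (bits) minus
  the child-size-weighted mean child entropy (Gini available via
  `impurity = "gini"`).  Genotype factors contribute their three
  level-subset bipartitions, booleans one split, and numeric covariates
  midpoint thresholds between sorted unique values (optionally
  restricted to fixed clinical cutpoints such as age 45 or CNE 95 via
  `cutpoints`).  Ties break by variable declaration order then
  enumeration order, so trees are fully deterministic.
* **Stopping** guards: children of at least `min_node_size` (20)
  subjects, maximum depth 6, positive gain.  These are safety limits;
  the tree's final size is decided by pruning.
* **Pruning** is cost-complexity: the weakest-link $\alpha$ sequence is
  computed from learning-set misclassification, and each candidate
  subtree's error is estimated by 10-fold cross-validation (a tree is
  regrown in every fold and pruned at the geometric-mean $\alpha$).  The
  subtree with the minimal cross-validated error wins; ties prefer the
  smaller subtree, and a 1-SE rule is available (`one_se = TRUE`).

The **cross-validated error metric defaults to binomial deviance**
(log-loss with Laplace-smoothed leaf rates) rather than misclassification
count, and this is a deliberate design choice.  In case-control samples,
an informative split can shift a node's case probability substantially
(say 0.33 to 0.69) without changing the majority class of either child,
in which case its misclassification saving is ~0 and misclassification
CV discards a real interaction.  Deviance is the cross-validated
counterpart of the information index used for splitting, is smooth in
the leaf probabilities, and in our calibration simulations both retains
planted structure (root-then-child recovery of a joint-OR-6 SNP×age
interaction in ~100% of runs at n = 1000) and prunes pure-noise trees to
the root in ~96% of runs.  `cv_metric = "misclassification"` restores
the classical behaviour.

Each evaluation subject is routed down the pruned tree; the terminal
node with the **lowest case fraction** is the reference (ties prefer the
larger node), and each node's crude OR against the reference is the 2×2
cross-product, optionally adjusted by logistic regression on node
indicators plus covariates.  Node risk tables are, by default, computed
on all routed subjects (learning + testing), matching how published
per-node counts cover the whole cohort; the testing set additionally
provides an internal verification error.

## The synthetic cohort generator

`simulateCaseControl()` draws a subject pool — per-SNP genotypes from
the inbreeding-extended Hardy–Weinberg law
($P(BB) = q^2 + fq(1-q)$ etc., $f = 0$ being exact HWE), covariates from
the distributions below — assigns disease from a logistic model
(intercept + per-SNP genetic-model effects + optional interaction and
covariate terms), and accrues exactly the target numbers of cases and
controls by rejection sampling.  Odds ratios are invariant under this
outcome-dependent sampling, so the specified ORs remain the estimand of
the crude analysis.  One master seed drives label-derived sub-streams
per stage, so a full two-stage study reproduces from a single integer.

Default covariate distributions emulate a noise-exposed industrial
workforce: age ~ N(48.32, 5.69) years; years of exposure ~ N(12.24,
5.75) truncated above 3 years (the usual eligibility floor); SPL ~
N(85.79, 5.13) dB(A).  The SPL parameters were calibrated once so that
the derived CNE distribution has mean ≈ 96.5 and SD ≈ 5.5 dB(A)·years
(the truncation makes E[10·log₁₀ years] ≈ 10.72, and variances add);
PPE use, smoking and drinking are Bernoulli(0.70/0.40/0.30), sex is 85%
male and ethnicity 95% Han, typical of such cohorts.  The disease-model
intercept is a free parameter (population prevalence is not identified
by a case-control design); defaults near −1 keep accrual efficient.

What the generator does **not** emulate: linkage disequilibrium between
panel SNPs (SNPs are independent), age-dependent audiograms (synthetic
thresholds are status-conditional Gaussians constructed only to exercise
the classifier), genotyping batch effects, or covariate–genotype
dependence (so passing tests demonstrate correctness of the estimators
under the assumed sampling model, not robustness to population
stratification — a confounded scenario is constructed explicitly in the
test suite instead).

## Calibration and test problem sizes

The package's statistical behaviour is verified by simulation at sizes
chosen to mirror the two-stage design it models:

* HWE QC: type-I exclusion 1% ± 0.5% over 5000 HWE SNPs at 252
  controls; power ≥ 99% against $f = 0.5$.
* Logistic estimation: exp(coefficient) equals the cross-product OR to
  $10^{-6}$ on 2×2-reducible data; adjusted recovery of ln OR within 3
  SE at n = 4000; ≥ 93% Wald CI coverage over 1000 simulated cohorts of
  n = 4000.
* Two-stage screen: 60-SNP panels with 6 planted effects at
  replication-scale ORs (1.44–2.66), 83/83 then 153/252 subjects, 200
  replicates; false positives stay below the binomial bound implied by
  the stage alphas, and power is reported.
* CART: split search equals exhaustive enumeration on all small
  fixtures; the planted SNP×age interaction (joint OR 6, n = 1000, a
  population cross-section of the exposed workforce) is recovered as a
  root-then-child pair in ≥ 90% of 200 replicates; pure-noise trees
  prune to the root in ≥ 90% of replicates.
* GRS dose–response: with six additive SNPs at per-allele OR 1.5 and
  risk-allele frequency 0.5 (which centres the score on the default
  bins, matching the GRS distributions such studies report), per-bin ORs
  are monotone and the trend test rejects at $p < 10^{-3}$ in ≥ 95% of
  n = 4000 replicates; under the null its type-I error is 5% ± 1%.

## Numerical and degenerate-input conventions

Zero cells: Haldane–Anscombe +0.5 on all four cells, flagged.  Tables
with no cases (or no controls) are errors, as is an empty GRS reference
bin or a one-leaf tree offered for risk estimation.  Monomorphic SNPs
return HWE $\chi^2 = 0$, $p = 1$, flagged.  $0\log 0 = 0$ in entropy.
Missing genotype calls are excluded per analysis (complete-case per
SNP); covariate-missing subjects are dropped only from adjusted fits;
CART subjects missing a split variable are unroutable and counted.  All
randomness (simulation, learning/testing split, CV folds) is seeded, and
identical seeds give byte-identical results.

## Known limitations

* Adjusted odds ratios from the original individual-level study data
  cannot be reproduced here — only their crude, count-derived
  counterparts are; the package's adjusted machinery is validated by
  parameter recovery on synthetic cohorts instead.
* No LD modelling, imputation, exact logistic regression, surrogate
  splits or multiway splits; genome-wide scale is out of scope.
* CART remains an exploratory, post-hoc tool; terminal-node ORs are
  descriptive and their intervals do not account for tree selection.
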