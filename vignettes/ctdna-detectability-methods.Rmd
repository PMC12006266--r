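---
title: "Methods: building and evaluating a tumor-expression classifier of ctDNA detectability"
author: "ctdnasig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and evaluating a tumor-expression classifier of ctDNA detectability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnasig)
```

## The problem

Circulating tumor DNA (ctDNA) — the tumor-derived minority fraction of
cell-free DNA in blood — is detectable in only part of early breast cancer
patients, and whether it is detectable carries prognostic information. This
package implements a complete workflow for asking whether the *tumor's own
expression profile* predicts ctDNA detectability: multi-cohort microarray
expression matrices are normalized per cohort, probes are ranked by a
meta-analysis of their differential expression between ctDNA-positive and
ctDNA-negative patients, a linear support-vector machine (SVM) is grown by
greedy wrapper feature selection, and the resulting classifier is evaluated
with diagnostic metrics, association tests, survival comparison and pathway
over-representation.

Because studies of this design rarely deposit their raw arrays or serum
digital-PCR calls, the package is built around a synthetic-data generator
with *known planted structure*: every downstream stage is testable against
ground truth without any download.

## The synthetic study generator

`simulate_study()` draws three cohorts (default sizes 25, 10, 13 with 7, 3
and 1 ctDNA-positive patients — a 10/35 training and 1/13 validation
prevalence; the split of the 10 positives across the two training cohorts is
proportional, as the pooled design leaves the per-cohort allocation free)
under the additive log2 model

$$x_{ps} = \mu_p + b_c + \delta_p\,\mathbb{1}[\text{ctDNA}^+_s]\cdot
  d\,\sigma + \varepsilon_{ps},\qquad \varepsilon_{ps}\sim N(0,\sigma^2),$$

with probe baselines $\mu_p \sim U(4, 12)$ (the usual post-normalization
log2 intensity range), a per-cohort batch shift $b_c \sim N(0, 0.5^2)$, a
planted standardized effect $d$ (default 1.5) with direction
$\delta_p \in \{+1, -1\}$ (default 70 up / 56 down among 126 differential
probes of 5000), and residual SD $\sigma = 1$. The same direction is planted
in every cohort — the model the meta-analysis assumes.

Clinicopathological covariates are independent Bernoulli draws with
frequencies matching an early breast-cancer surgical series (e.g. 83% ER+,
17% HER2+, 14% grade 3); they are deliberately independent of ctDNA status,
mirroring a study in which no conventional parameter was significantly
associated with detectability. Recurrence-free survival uses an exponential
baseline hazard (0.0015/month, i.e. ~86% event-free at 100 months for
ctDNA-negative patients) with a proportional hazard ratio (default 3) for
ctDNA-positive patients, administrative censoring uniform over a 10–147
month follow-up window, and optional early drop-out (default probability
0.1). All draws flow from one seeded generator: identical seed and
configuration give bit-identical output.

What the generator does *not* emulate: probe-sequence affinity biases, raw
array images (background correction), correlated gene modules, covariates
confounded with ctDNA status, and non-proportional hazards. Tests passing on
this generator therefore demonstrate the *machinery* (ranking power,
selection behavior, calibration), not performance on real tumors.

`simulate_probe_level()` generates the probe-level fixture for the
summarization stage (a shared per-probeset, per-sample signal plus fixed
probe affinities plus noise), and `simulate_dpcr()` draws Poisson mutant /
wild-type copy counts, the counting model of chip digital PCR.

## Simplified RMA normalization

Cohorts are normalized independently — never pooled — matching the
per-dataset processing of multi-reagent microarray studies.
`quantile_normalize()` forces all samples of a cohort onto the common
rank-wise-mean distribution; tied values within a sample receive the mean of
the rank-wise means over their tied ranks, which makes the transform
deterministic and idempotent. `median_polish()` (Tukey's alternating median
sweeps, rows before columns, via `stats::medpolish`; tolerance 1e-6, at most
10 sweeps) supplies the robust additive decomposition, and
`rma_summarize()` chains log2 → quantile normalization → per-probeset median
polish, reporting overall + column effect as the probeset expression.

The exponential-signal/Gaussian-noise background-correction convolution of
full RMA is deliberately omitted: it operates on raw probe-cell intensities
that summarized expression studies do not carry, and every downstream stage
consumes normalized values only. The stage is therefore documented as
"simplified RMA". Note one numerical consequence of quantile normalization:
a per-sample additive shift shared by all probes is removed, so exact
recovery of a simulated per-sample signal is only observable with
`normalize = FALSE` (the pure additive-model path used in the identity
tests).

## Meta-analytic probe ranking

Within each training cohort, every probe gets a Hedges-corrected
standardized mean difference $g$ (ctDNA-positive minus ctDNA-negative, small
sample correction $J = 1 - 3/(4(n-2)-1)$) with sampling variance
$(n_1+n_0)/(n_1 n_0) + g^2/(2(n_1+n_0))$. Cohorts are combined by the
closed-form DerSimonian–Laird (DL) random-effects estimator; a fixed-effect
(FE) inverse-variance variant is available through `meta_model = "FE"`.
Probes with a two-sided combined $p < \alpha$ (default 0.010) are retained,
sorted by $p$, with ties broken by |combined effect| then probe ID — a
stated, deterministic rule.

Two design points deserve emphasis:

* **Effect measure.** The upstream study names only "a meta-analysis
  package"; an effect-plus-variance measure is required for any such
  integration, and Hedges g is the standard choice for two-group expression
  contrasts at small n. The per-cohort test statistic is then the
  meta-analytic z, not a per-cohort t-test.
* **DL vs FE with two cohorts.** DL estimates the between-cohort variance
  $\tau^2$ from Q with $k - 1 = 1$ degree of freedom; at two cohorts this
  estimate is mostly sampling noise, and spuriously large $\hat\tau^2$
  values cost substantial power (a well-known small-k limitation of
  random-effects meta-analysis). DL remains the default for fidelity to
  standard practice, but power-sensitive checks in this package (planted
  probe recovery) use the FE switch; an a-priori power calculation for the
  default design (7+3 positives vs 18+7 negatives) gives roughly 85% power
  at $p<0.010$ for a 1.5-SD effect under FE, rising to ~97% at 2.0 SD,
  which is why the recovery checks plant a 2.0-SD effect.
* **Calibration.** The $g^2$ term in the effect variance shrinks extreme
  statistics, so at $n = 35$ the null candidate fraction sits *below*
  $\alpha$ (about 0.5–0.8 of it) and approaches $\alpha$ from below as
  groups grow: the ranking is conservative, never anti-conservative. Tests
  assert exactly that behavior.

Constant (zero-variance) probes cannot yield a finite standardized effect;
they are dropped with a warning rather than imputed.

## The classifier

`sequential_forward_select()` performs single-pass greedy wrapper selection
in meta-analysis rank order: a candidate probe is kept only if the
leave-one-out cross-validated (LOOCV) accuracy of the linear SVM on the
pooled training samples *strictly* increases (a non-strict rule would
accumulate unbounded plateau probes). Selection stops at LOOCV accuracy 1,
exhausted candidates, or `max_probes`. The baseline for the first acceptance
is the majority-class accuracy of a featureless classifier, and with
`max_probes = 0` the model degrades to exactly that majority rule — the
pipeline still runs.

Numerical and methodological choices, all surfaced in `svm_config()`:

* Linear kernel, cost 1, balanced class weights — deterministic,
  appropriate at 10 positives vs 25 negatives; unstated upstream and
  therefore chosen for small-n robustness.
* Per-cohort standardization (probe-wise center/scale within cohort) before
  pooling: the minimal cross-cohort scale alignment when cohorts were
  processed with different reagents.
* Standardization is *refit inside every LOOCV fold* (leakage-free); a
  global-standardization variant would be the other defensible reading.
* Decision ties (value exactly 0) call negative — conservative toward the
  majority class.

`predict()` standardizes a new cohort with its own parameters (the same
alignment applied to training cohorts), applies the training-time pooled
standardization and the linear rule.

## Evaluation statistics

`contingency_table()` / `diagnostic_metrics()` compute accuracy,
sensitivity, specificity, PPV and NPV as percentages, flagging
zero-denominator metrics as undefined rather than 0. The chi-square test is
Pearson's *without* continuity correction — the variant that reproduces the
published association p-values (0.1644 for tumor diameter; 0.0146 for the
classifier/ctDNA association in a 13-patient validation set) from their
count tables; Yates' correction does not. Fisher's exact test is the
standard two-sided hypergeometric enumeration. `odds_ratio_woolf()` returns
the sample odds ratio with the Woolf log-normal interval, and flags any
zero cell as separation instead of printing an astronomically large
pseudo-number; `logistic_fit()` does the same for ML logistic fits
(separation detected from pinned fitted probabilities plus exploding
coefficients), reporting both Wald and likelihood-ratio p-values since
published tables rarely say which was used.

One data note: in the source tables for the validation set, the printed
contingency cells contradict the printed metrics under their own headers;
the reconciled table (tn = 11, fp = 1, fn = 0, tp = 1) is forced by the
12/1 ctDNA margin together with the stated sensitivity/specificity/PPV, and
is the fixture used here.

`km_curve()` / `logrank_test()` wrap `survival::survfit` / `survdiff`
(events precede censoring at tied times; Greenwood errors retained), with
`rfs_at()` for right-continuous step evaluation. `hypergeom_enrich()`
implements both the standard upper-tail hypergeometric p and the EASE
variant (count reduced by one — never more significant than the standard
p), with Bonferroni and Benjamini–Hochberg adjustment; the background
defaults to all genes in the annotation, since the original analysis
background is unrecoverable. `maf()` and `ctdna_call()` encode the serum
digital-PCR rules: MAF = 100·mutant/(mutant+wild-type), positive on one or
more mutant alleles; `ctdna_call_patient()` OR-combines the three hot-spot
assays per patient, since the per-assay rule is what the assay definition
states.

## Problem sizes used in the shipped checks

The test-suite simulations use 300–5000 probes, the study's cohort sizes
(25/10/13), and 5–20 seeds per Monte-Carlo property; the acceptance script
uses 10 seeds for recovery measures and 30 for log-rank power. These sizes
were chosen so each property estimate's Monte-Carlo error is comfortably
inside the asserted band while the whole suite remains quick to run.

## Known limitations

* Cohort batch effects are additive global shifts; real batch effects are
  probe-specific.
* The greedy wrapper explores a single forward pass; the selected probe set
  is a local optimum by construction.
* DL meta-analysis at k = 2 is structurally noisy (see above); with more
  cohorts the default becomes well-behaved.
* Real-data headline results of the motivating design (counts of candidate
  and selected probes, specific gene identities, survival p-values)
  require the original patient data and are not reproduction targets; the
  package's claims are about the machinery, verified against planted truth
  and independent oracles.
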