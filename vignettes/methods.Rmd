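---
title: "Models and methods behind lupusnr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lupusnr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lupusnr` analyses drug non-response in longitudinal lupus nephritis
cohorts. This vignette explains the statistical models each stage assumes,
the tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where more than one reasonable option existed.

## Clinical labelling

A patient's response to a drug is judged on the *sustained* SRI-4
composite: from some visit at least 3 months after the first visit on the
drug, SLEDAI must have fallen by at least 4 points from baseline with no
meaningful PGA worsening, and the state must persist at every later
on-drug visit. Two operationalisations deserve comment.

* **PGA worsening.** "No worsening" is implemented as a PGA increase
  strictly below 0.3 (on the 0–3 scale), the standard SRI-4 convention;
  the threshold is the `pga_worsening` argument.
* **BILAG.** The BILAG clause (no new A, at most one new B) is applied
  only when BILAG columns are present, and can be switched off
  (`use_bilag = FALSE`) because many cohort tables do not carry BILAG at
  all. Whether the clause should bind is genuinely open; exposing it as a
  flag makes either reading reproducible.

The renal (UPCR) label requires the protein/creatinine ratio to be
*reduced* below 500 mg/g — which we read as requiring a baseline at or
above 500 — and then held below 500 from some month-3+ visit through the
last on-drug visit. Patients already below 500 throughout are labelled
responders but flagged `already_low`, since "reduced" never happened; the
flag lets analysts drop them.

Cohort summaries use the two test families appropriate to each variable
type: two-sided Wilcoxon rank-sum for continuous variables (exact when
both groups have ≤ 25 observations and no ties force the normal
approximation; continuity-corrected otherwise) and two-sided Fisher exact
tests for categorical ones. Patient-level variables are collapsed to one
row per patient first; sample-level variables use every visit. Rows with a
missing tested value are dropped per variable and counted in `n_missing`
rather than imputed.

## Moderated differential expression

Longitudinal designs repeat samples within patients, so per-gene ordinary
least squares understates uncertainty. Rather than fitting a random-effect
model per gene — expensive and fragile at a few dozen patients — the
package uses the consensus-correlation device: one intra-patient
correlation ρ pooled across genes, then generalized least squares per gene
under the working covariance σ²[(1−ρ)I + ρJ] within each patient block.

* ρ is estimated from OLS residuals as the mean within-block
  cross-product over the residual variance, per gene; per-gene estimates
  are pooled by a 15%-trimmed mean on the atanh scale. The trimming keeps
  a handful of wild per-gene estimates (low-variance genes) from moving
  the consensus.
* Patient is deliberately **not** a fixed effect: the response contrast is
  a between-patient comparison and patient dummies would absorb it
  entirely.
* The design adjusts for sex, SLEDAI, prednisone dose and drug dose
  (continuous), with covariates constant in a subset silently dropped.
  Race is excluded by default: in cohorts of this shape it is confounded
  with the response groups, and adjusting for it would remove part of the
  signal being estimated. Dose covariates enter as continuous values —
  the natural scale when doses are titrated — though a user can pass any
  design matrix.

Whitening uses the closed-form inverse square root of the
block-equicorrelation matrix, `a(I − P₁) + bP₁` with `a = 1/√(1−ρ)` and
`b = 1/√(1−ρ+mρ)` for a block of size m, so the per-gene fits are a
single multi-response least squares call.

Empirical-Bayes shrinkage assumes the true variances follow a scaled
inverse-chi-square prior, equivalently `s²_g ~ s₀² F(d_g, d₀)` marginally.
`(d₀, s₀²)` are fitted by matching the mean and variance of `log s²_g`
(digamma/trigamma identities), with the trigamma equation inverted by
Newton iteration at tolerance 1e-8. Numerical edge cases:

* excess log-variance ≤ 0 (no spread beyond chi-square sampling noise)
  maps to the infinity sentinel `d₀ = 1e6` with `s₀²` the bias-corrected
  geometric mean — and when the variances have literally zero spread the
  correction is skipped so `s₀²` equals the common variance;
* `d₀` is capped at 1e6 everywhere, keeping the t degrees of freedom
  finite;
* constant gene rows are flagged and excluded from testing and from the
  Bonferroni multiplier.

Significance is Bonferroni at strict p < 0.05 — conservative on purpose,
matching how such signatures are usually reported — and the contrast is
oriented so positive log-fold-changes mean *higher in non-responders*
("up" signature genes).

## GSEA comparison and the ratio score

Cross-drug signature similarity uses the weighted Kolmogorov–Smirnov
running sum over a fold-change-ordered gene list. The weight exponent
defaults to p = 1 (weights = |log fold change|), with p = 0 available
because the unweighted statistic is hand-checkable and some published
scores use it; which exponent produced any given published value is
usually not stated. Permutation inference randomizes gene labels
(`n_perm = 1000` by default; a seed is mandatory), NES divides ES by the
mean |permuted ES| of the same sign, and the permutation p uses the
(1 + count)/(1 + n) estimator so it is never exactly zero.

The ratio score — mean log2 expression over up-genes divided by mean over
down-genes — assumes positive log-scale values; matrices anchored near
zero make the denominator unstable, so a non-positive down-gene mean is an
error instructing an explicit positive `offset` rather than a silent
re-anchor.

## Deconvolution and rich/poor stratification

Cell-type fractions come from non-negative least squares on the signature
basis genes, renormalized to sum to one. NNLS is the package's solver of
choice for the linear mixture model: convex, deterministic, assumption-
light, and its recovery is directly verifiable on synthetic mixtures
(noiseless round trips recover fractions to numerical precision). Types
that cannot circulate in blood can be excluded post-fit, with fractions
renormalized over the remaining types.

Stratification is at the *patient* level — the median split uses patient
mean fractions, while response rates are computed over samples — because
the clinical claim ("rich patients respond worse") is about patients, and
visits per patient vary. Ties at the median go to "poor",
deterministically. Whether per-sample fractions would be more appropriate
is open; the choice is a documented argument.

## Single-cell stage

QC evaluates every rule on the pre-filter statistics, so rule order cannot
change the kept set: mito fraction > 25%, ribo fraction > 25%, features or
totals outside the 0.5–99.5 percentile band, < 200 features, Gini or
Simpson diversity < 0.8. The two diversity indices needed definitions:
`simpson` is the Gini–Simpson index 1 − Σp² and `gini_diversity` is one
minus the Gini coefficient, both over *detected* genes only so sparsity
does not dominate. Both thresholds are arguments because a 0.8 cut tuned
on real droplet data need not transfer to other platforms. Mito/ribo
genes are recognised by configurable name prefixes (`^MT-`, `^RP[SL]`).
Doublet removal, integration and graph clustering are intentionally out of
scope: the synthetic data carries ground-truth cluster labels, and on real
data those steps belong to the established single-cell toolchains.

Normalization fixes each cell's total at 1000 counts then applies
log(1+x). Module scores subtract expression-matched background: genes are
binned into 24 mean-expression bins, each signature gene draws 100 control
genes from its bin (never from the signature; with replacement when a bin
is thin, widening to neighbouring bins when the signature monopolizes its
bin), and the score is the per-cell set mean minus the pooled control
mean. Control sampling has its own seeded RNG so scores are reproducible.

Cluster markers are cluster-vs-rest two-sided Wilcoxon tests with
Bonferroni correction over genes within a cluster, using the exact
distribution when both groups are small and tie-free. The cluster-level
summary reports, per major cell type, the **maximum of subcluster mean
scores** and the argmax subcluster, with negative means kept as-is — no
clipping — since a maximal negative mean is itself informative.

## In-silico druggability

Circuits are signed acyclic receptor→effector graphs. Node input values
come from *reference-anchored rank scaling*: each gene is mapped to (0,1)
by its mid-rank among the reference samples, `(#{ref < x} +
(#{ref = x}+1)/2)/(n+1)`, and a node takes the mean of its member genes.
Anchoring matters: multiplying every sample's target expression by 0.1
leaves within-gene sample ranks unchanged, so perturbed values are
re-ranked against the *unperturbed* distribution — that is what lets a
uniform knock-down move node values down. Propagation follows
`S_n = v_n (1 − Π_a (1 − S_a)) Π_i (1 − S_i)` in topological order;
signals stay in [0,1], receptors pass their value through, a node with
only inhibitory inputs is silent, and cycles are an error naming the
offending nodes.

The response score sums |activity after − before| over circuits. Published
descriptions of such scores are ambiguous between circuit-level and
gene-level change; the circuit-activity sum is implemented as the primary
definition because activity is the mechanistic model's native output, and
per-circuit deltas are returned alongside so a per-node variant can be
assembled if wanted. "Favorable" response is a score at or
above the mean over all patients supplied (inclusive, so an all-equal
cohort is 100% favorable); the grouping for the reported rate (typically
non-responders) is a filter, the threshold is always cohort-wide.
The ×0.1 inhibition factor is exposed but carries no claim of
pharmacological realism.

## Nested cross-validation

Folds assign *patients*, never samples: a greedy balancer visits groups
from largest to smallest (ties shuffled under the seed) and places each in
the fold that least disturbs the per-fold class targets, with ties going
to the emptiest fold. Five outer folds; hyperparameters tuned by 10-fold
inner CV repeated 5 times on each outer-train; the inner selection metric
is the mean MCC, matching the outer ranking metric (the alternative —
accuracy inside, MCC outside — optimizes the wrong quantity under class
imbalance). MCC is defined as 0 when any confusion marginal is empty.
The eleven-model zoo delegates fitting to the standard implementations
(logistic regression, LDA, gradient-boosted trees, random forest, k-NN,
linear/radial SVM, single-layer neural net, naive Bayes, boosted stumps,
and a boosted additive model via a linear booster); the zoo is a config
argument, and the package's own contribution is the grouped fold
construction, the tuning loop and the MCC accounting. Features default to
the top-10 signature genes by adjusted p.

## The synthetic cohort: what it emulates, and what it does not

The bulk generator produces log2-scale expression
`y = μ_g + b_i + covariates + planted effect + ε` with patient intercepts
`b_i ~ N(0, σ_p²)` and noise `ε ~ N(0, σ_e²)`; defaults σ_p = σ_e = 0.5
log2 units give an intra-class correlation of 0.5, a realistic magnitude
for repeated blood draws, and planted effects of δ = 1 log2 unit are at
the upper end of what bulk signatures show. Planted up/down genes shift
only in non-responders *of the matching drug*, so drug specificity is true
by construction. Clinical series are generated consistently with the
labels: responders' SLEDAI drops ≥ 4 by month 3 and stays down, UPCR falls
below 500, and so on — which is what lets the labelling stage be tested
for exact agreement with planted arms. The single-cell generator uses
near-flat gene profiles (Poisson counts, ~15k mean library) with a 2×
planted program in one cluster, 8%/15% mito/ribo count shares for good
cells and ~45% mito for planted low-quality cells; profiles are kept even
enough that good cells clear the 0.8 diversity cut with margin, because a
generator whose healthy cells fail its own QC tests nothing.

What the generator does **not** emulate: microarray probe effects, batch
structure, ancestry-linked expression, realistic single-cell
overdispersion and doublets, or dose-response pharmacology. Passing tests
therefore demonstrate correctness of the estimators under the stated
models — calibrated type-I error, parameter recovery, oracle agreement —
not performance on any real cohort.

## Problem sizes and numerical settings used by the test suite

The packaged checks run at sizes chosen to finish in seconds to minutes on
one core while keeping the statistical claims meaningful: null DE
calibration uses 100 cohorts of 25 patients/arm × 3 visits × 200 genes;
hyperparameter recovery uses 2000 simulated variances; planted-signature
recovery uses 30 patients/arm with a single visit and σ_p = 0.25 (the
recovery condition names only the residual SD, and patient intercepts
would otherwise dominate the contrast at desk scale); propagation is
verified against brute force on 1000 random 8-node circuits; module-score
calibration uses 1000 cells × 20 random 50-gene sets; nested-CV
benchmarks use 100 samples from 50 patients. Newton inversions run at
tolerance 1e-8; oracle agreements are asserted at 1e-10 to 1e-12.

## Known limitations

* The consensus correlation is attenuated in very small cohorts (few
  patients, few visits); the DE stage remains calibrated in the tested
  regimes, but ρ itself should not be read as an unbiased ICC estimate.
* NNLS deconvolution shares the linear-mixture assumption of
  reference-based methods but none of the feature-selection or batch
  machinery of production deconvolvers; basis quality is the user's
  responsibility.
* The druggability stage is a mechanistic toy: toy circuits, rank-scaled
  inputs, a fixed ×0.1 knock-down. It ranks patients by how strongly
  their circuits run through the targets; it does not predict clinical
  effect sizes.
* Clinical labelling assumes complete SLEDAI/PGA series; missing-visit
  handling is deliberately left to the analyst.
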