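---
title: "Pre-filter benchmarking for sparse feature selection: models and methods"
author: "prefilterBench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-filter benchmarking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefilterBench)
```

## The problem

Case-control expression studies routinely measure tens of thousands of
features (genes, microRNAs) on tens of samples. Embedded feature-selection
methods such as L1-penalized logistic regression can cope with that
imbalance, but their cost and stability improve markedly if the feature
space is *pre-filtered* first. Two families of pre-filters dominate
practice:

* **statistical** — keep features differentially expressed between the
  two classes (two-sample t-test at a threshold);
* **biological** — keep features connected to prior disease knowledge:
  genes annotated to functional terms over-represented in a list of known
  disease ("seed") genes, or microRNAs with a validated target among the
  seed genes.

This package builds, from one paired mRNA/microRNA study, the four
canonical dataset types per layer — raw (**type 1**), statistically
filtered (**type 2**), biologically filtered (**type 3**), and the
intersection of both (**type 4**; for mRNA, types 3 and 4 come in one
variant per term collection: BP, MF, CC, Pathway, giving 10 mRNA + 4
microRNA datasets) — then runs the same selection and evaluation machinery
on each so the pre-filters can be compared like for like: by feature
reduction, cross-validated AUC and precision, overlap of the selected
sets, and coverage of the seed list's enriched terms.

## Statistical primitives

**Differential expression.** Per feature, a two-sided two-sample t-test.
The package defaults to Welch's unequal-variance form — the safer choice
when nothing is known about per-class variances — with Student's pooled
form available (`varEqual = TRUE`). Thresholds are *inclusive*
(`p <= alpha`, default `alpha = 0.05`). Degenerate rows (zero variance in
both classes) return `p = 1` when the means agree and `p = 0` with an
infinite statistic when they differ; both conventions are documented in
`twoSampleT()` and exercised in the tests.

**Enrichment.** For a gene list of size $d$ drawn from a universe of $b$
genes, a term with $a$ annotated genes and $n$ list members annotated, the
enrichment p-value is the hypergeometric upper tail
$P(X \ge n) = \sum_{k \ge n} \binom{a}{k}\binom{b-a}{d-k} / \binom{b}{d}$,
the standard over-representation convention; the strict tail $P(X > n)$ is
available via a flag. Three choices deserve emphasis:

* the universe $b$ is **explicit**: collections are restricted with
  `restrictToUniverse()` to the features actually measured, so the test
  background is never an accident of the annotation file;
* no multiple-testing correction is applied by default — the pre-filters
  treat `alpha` as a plain per-term threshold — with Benjamini–Hochberg
  available behind `adjust = "BH"`;
* output ordering is total and deterministic (p-value, then term
  identifier), so downstream results are reproducible.

Only the seed list is enriched; enriching the whole measured universe
against itself is degenerate (every term has $n$ at its expectation and
$p$ near 1) and is deliberately not part of the type-3 construction.

## Dataset construction

Type 2 keeps features with $p \le \alpha_{DE}$. Type 3 (mRNA) enriches
the seed list against one collection and keeps every measured feature
annotated to at least one enriched term; type 3 (microRNA) keeps
microRNAs with at least one validated target among the seed genes. Type 4
is formalized as the **exact intersection** of the type-2 and type-3
feature sets at identical thresholds: the set-algebra identity
`type4 == type2 ∩ type3` is then testable, and it matches the narrative
reading "differentially expressed features that also carry the disease
annotation". Whether one instead re-runs enrichment on the DE list is a
genuinely open design point; the intersection was chosen because it is
order-free and auditable.

Empty outcomes are representable: a filter that removes everything yields
a valid zero-row dataset with a warning, and downstream stages must skip
it explicitly (selection and cross-validation refuse empty datasets by
name; the pipeline records a skipped row rather than aborting).

## Feature selection

The engine is an in-package L1-penalized logistic regression,
$\min_{w,b}\; L(w,b) + \lambda \lVert w\rVert_1$ with $L$ the mean
logistic log-loss and the intercept unpenalized. Numerical conventions:

* **Solver.** Monotone FISTA: proximal gradient with Nesterov
  acceleration, backtracking line search, and a descent restart that
  guarantees the objective never increases. The initial step uses a
  power-iteration estimate of $\lVert [X\,\mathbf 1]\rVert_2^2/(4N)$ — the
  Frobenius bound is far too loose on wide designs — and backtracking
  protects against any underestimate.
* **Convergence** is declared by the KKT residual (subgradient
  optimality) falling below `tolerance` (default `1e-6`); non-convergence
  returns the fit with `converged = FALSE` plus a warning, never silently.
* **Standardization.** Features are z-scored inside the solver (training
  folds only during cross-validation) so one λ is comparable across
  features; weights are back-transformed, and $|w_j| < 10^{-9}$ after
  back-transformation counts as zero for support extraction.
* **λ choice.** `lambdaMax()` (the largest absolute loss gradient at the
  all-zero solution, with the intercept at the prevalence logit) tops a
  50-point log-spaced grid down to `1e-3 * lambdaMax`. The default
  strategy picks λ by stratified 5-fold mean held-out log-loss within the
  training data, breaking ties toward the larger (sparser) penalty, then
  refits once on all training samples; a fixed-λ strategy is available.
  The path fits that only *score* candidate penalties run at a looser
  tolerance (`1e-4`, 100 iterations, warm-started along the grid) because
  held-out loss is insensitive to solving them to full precision; the
  reported fit always uses the strict settings.
* The reported feature set comes from a **full-data fit** at the chosen
  λ; per-fold fits are used only for performance metrics. This matches a
  reporting style with a single selected-feature count per dataset.

## Evaluation

Cross-validation is stratified (each class dealt round-robin across
folds): with a strongly imbalanced design, unstratified folds risk a
single-class fold in which neither AUC nor a meaningful fit is defined.
Held-out scores are pooled — every sample scored exactly once by the fold
that excluded it — and AUC and precision are computed on the pooled
scores; per-fold values are reported alongside. AUC uses the midrank
estimator, which equals exhaustive positive-negative pair comparison with
ties counted one half. Precision is TP/(TP+FP) at probability threshold
0.5 (positive class = disease); when nothing is called positive the value
is an explicit `NA`, never a silent zero. Wall-clock time is recorded but
is informational only. Feature reduction is
`100 * (raw - kept) / raw` percent.

Overlap analysis counts pairwise intersections among selections within a
layer and reports features appearing in at least two selections. Term
coverage enriches the seed genes and the selected genes separately against
the same collection and reports
$|E_{seed} \cap E_{sel}| / |E_{seed}|$ — the *enrichment* reading of
"the selection covers the seed list's biology"; mere annotation overlap
would be a weaker statement and is not what is computed.

## The synthetic study generator

`simulateStudy()` emulates the shape of a paired two-class microarray
study: class-conditional Gaussian log-intensities with per-feature
baseline $\mu_f \sim N(7, 2^2)$ and unit within-class standard deviation;
planted differential features get an additive `effectSize`·σ shift in the
case class. This is the simplest model satisfying the t-filter's
assumptions, which is exactly the structure the statistical pre-filter
presumes. Around the expression layers it plants the knowledge structure
the biological filters need: a seed list drawn from the planted genes with
probability `seedEnrichmentBias`, per-collection disease terms whose
members come from the seed∪planted pool with probability
`diseaseTermPurity` (default 0.8, guaranteeing a recoverable enrichment
signal with a tunable margin), and a target map whose planted-microRNA
pairs point at seed genes with probability `targetBias`.

Defaults are the test-scale study used throughout: 30+30 samples, 500
genes (10% planted), 60 microRNAs (15% planted), effect size 1.5σ, four
collections of 20 terms (sizes 5–25, 4 disease terms each), 40 seed
genes at bias 0.9, 300 target pairs at bias 0.9. At these settings the
two-sample t-test's power per planted gene exceeds 0.99, so near-complete
type-2 recall is an analytic expectation, not a tuned outcome. A single
RNG stream with a fixed generation order (labels, mRNA, microRNA, seeds,
collections, targets) makes every study bit-reproducible from its seed;
the pipeline derives all stage seeds from one master seed.

What the generator does **not** emulate: array artifacts (dye bias,
batch effects, missing probes), correlated co-expression blocks,
heavy-tailed or heteroscedastic noise, and realistic annotation overlap
structure. Tests passing on these studies therefore demonstrate the
machinery — calibration of the filters, recovery of planted signal,
correctness of the algebra — not performance on real arrays.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use deliberately small
instances chosen to exercise every code path at interactive speed: the
default 500-gene study for recovery checks (20 replicate seeds,
median-summarized), 10,000 null genes for filter calibration (pooled over
3 studies), exhaustive hypergeometric scans to universe size 60 plus 1,000
random cases to 200, and a 120-gene pipeline run for structural checks.
These sizes give the binomial/continuity margins the assertions need while
keeping a full run in minutes.

## Known limitations

* The solver is dense; it is sized for thousands of features, not
  millions. Coordinate descent with screening rules would be the next
  step if the feature spaces grew by an order of magnitude.
* Near-separable fits at tiny penalties converge slowly (the optimum
  drifts toward infinity as λ→0 on separable data); such fits are
  reported honestly as non-converged when the iteration cap is hit.
* Probe-to-feature collapse refuses ambiguous probes (one probe, two
  features) rather than guessing; mean and median are the only collapse
  rules offered.
* The evaluation reports pooled and per-fold metrics but no confidence
  bands; the package takes no position on fold-to-fold variance.
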