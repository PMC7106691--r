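---
title: "Methods: two-level hierarchical modeling of miRNA-mRNA pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-level hierarchical modeling of miRNA-mRNA pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(himpair)
```

## Model and assumptions

`himpair` identifies miRNA–mRNA pairs associated with a binary disease
status from paired (tumor / adjacent-normal) expression matrices. The model
has two levels. The *mechanistic* level fits, for each disease-associated
mRNA $j$,

$$ \mathrm{mRNA}_j = \alpha_0 + \textstyle\sum_p \alpha_p\,\mathrm{miRNA}_p + e_j, $$

a lasso-penalized linear regression on all disease-associated miRNAs,
yielding a linear predictor $\eta_j$ (the miRNA-explained component,
intercept included) and residual $e_j$. The *clinical* level fits a
lasso-penalized logistic regression of status $Y$ on all $\eta_j$, all
$e_j$, and the log expression of every significant molecule that the
mechanistic level left out ("orphans"):

$$ \operatorname{logit} P(Y=1) = \beta_0 + \sum_j \beta_{\eta j}\eta_j
   + \sum_j \beta_{e j} e_j + \sum_k \beta_k\,\overline{\mathrm{mRNA}}_k
   + \sum_l \beta_l\,\overline{\mathrm{miRNA}}_l. $$

Selection of $\eta_j$ means the miRNA-driven part of mRNA$_j$ carries
disease signal, so the pair $(m, j)$ is emitted for every miRNA $m$ in the
lasso support of mRNA$_j$; selection of $e_j$ means the disease effect of
mRNA$_j$ bypasses its miRNAs, and no pair is emitted for it.

Two assumptions deserve emphasis. First, samples enter the logistic model
as independent observations, not as conditional (matched) pairs; the
package's dependence diagnostic (`dependence_report()`) — the per-feature
correlation between tumor and matched normal vectors across patients —
supports this when most |r| are small. Second, all significant miRNAs are
offered as predictors to every mRNA; no target-database prefiltering is
applied, so supports are statistical, not curated, objects.

## Workflow and conventions

1. **Alignment.** Matrices are aligned to the design; a patient missing
   either tissue loses both samples (with a warning). At least 3 complete
   pairs are required.
2. **Normalization.** TMM scaling factors (trimmed mean of M-values:
   reference sample by upper-quartile closest to the mean upper-quartile;
   30% two-sided trim on M, 5% on A; inverse-asymptotic-variance weights;
   factors rescaled to geometric mean 1), then division by effective
   library size, rescaled to the geometric-mean depth.
3. **Log transform.** $\log_2(x + 1)$. Base 2 and pseudocount 1 are the
   field's conventional defaults; both are configurable.
4. **Paired testing.** Per feature, a paired t-test on within-patient
   differences of normalized log values; Benjamini–Hochberg adjustment is
   applied *per matrix* (mRNAs and miRNAs separately), matching the
   convention of reporting selected-feature counts per platform. Passing is
   strict: FDR < threshold. Fold changes are deliberately computed on the
   *raw* scale as median(tumor)/median(normal), so the test and the fold
   change honor different conventions on purpose; a zero normal median
   yields a signed `Inf` with an explicit flag, never a silent clip.
5. **Mechanistic fits**, 6. **clinical fit**, 7. **pair emission** as
   above, followed by reporting in the `pairs (#mRNA) (#miRNA)` convention
   at each stage.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fdr_threshold` | 0.05 | strict BH-FDR cutoff for feature pre-selection |
| `log_base`, `pseudocount` | 2, 1 | log transform (log2 units downstream) |
| `lambda_rule` | `cv_min` | penalty rule: CV minimum, 1-SE, or fixed |
| `cv_folds` | 10 | CV folds, assigned at the *patient* level |
| `seed` | 1 | master seed; every stochastic step derives from it |
| `correlation_threshold` | 0.5 | \|r\| cutoff of the baseline screen |
| `dependence_threshold` | 0.3 | \|r\| cutoff of the dependence diagnostic |
| `max_missing_fraction` | 0.9 | sparse-feature dropping threshold |

`cv_min` is the default because the fitting tool's CV minimum is the common
default; `cv_1se` yields sparser supports (see Limitations). Cross-validation
folds keep a patient's two samples together so the paired structure never
leaks across folds — a deliberate strengthening over sample-level folds.
Each mRNA's folds are seeded by a stable hash of its identifier XORed with
the master seed, making results independent of iteration order and safe to
parallelize.

## Numerical choices

- **Exact decomposition.** After fitting, $\eta$ is nudged by at most one
  ulp so that $\eta + e$ reproduces the observed log value *bit-exactly*
  (a Sterbenz reconciliation: the residual is small relative to log-scale
  abundances, so the second subtraction is exact). The package asserts
  $\max |y - (\eta + e)| = 0$ on every fit.
- **Penalized-fit precision.** Gaussian fixed-penalty fits use a coordinate
  descent threshold of 1e-10, so Karush–Kuhn–Tucker conditions hold to
  1e-6 on the original scale; cross-validated paths and logistic fits use
  1e-8, ample for their tolerances and robust against stalling near the
  saturated end of the path.
- **Standardization.** Predictors are standardized internally for
  penalization and coefficients are reported on the original scale; the
  intercept is never penalized. Both η/e and molecule columns share one
  global penalty in the clinical fit — the simplest faithful reading of a
  single lasso — and η and e of the same mRNA are selected independently,
  as the model is written (no group constraint).
- **Degenerate inputs.** Zero-variance difference vectors get p = 1 with a
  degeneracy flag (never NaN); zero-variance responses yield intercept-only
  fits; constant vectors in the dependence diagnostic are recorded as r = 0
  and flagged; a single predictor column is padded with an all-zero dummy
  for the solver and the dummy is stripped from results. Small cohorts
  (n < 2 × folds) fall back to deterministic leave-one-out CV with a
  message.
- **Selection order.** `select_significant()` orders by ascending FDR, then
  feature ID — a total, reproducible order.

## The simulator

`simulation_truth()` + `simulate_dataset()` generate paired cohorts with
known ground truth, on the log2 scale: per-feature baselines are
Uniform(4, 10); miRNA abundance adds a tumor-only shift (disease channels
only) and Gaussian noise; mRNA abundance is baseline + A × (centered miRNA
abundance) + residual-channel shift + noise; abundances are exponentiated,
scaled by per-sample library-size factors (log-uniform in [0.5, 2], so TMM
has something to correct; `vary_libsize = FALSE` isolates model behavior),
and rounded to counts.

Lognormal-then-round noise was chosen over an explicit negative binomial
deliberately: it produces overdispersed, count-like data while keeping the
log-scale linear model *exactly* correct, so mechanistic recovery can be
scored against a well-defined truth. Three disjoint disease channels exist:
mRNAs whose effect flows through their regulators (the η channel — each
regulator receives a shift of `effect_size × sign(coefficient)`, so all
regulators push their mRNA the same way: coherent dysregulation), mRNAs
with a direct residual-channel shift, and directly shifted miRNAs. The
bundled presets (`null`, `easy`, `default`, `hard`: 30 patients, 200 mRNAs,
60 miRNAs) activate only the η channel — 5 mRNAs × 3 disjoint regulators =
15 true pairs — at shifts 0/2.0/1.5/0.75 log2 units and noise sd
0/0.25/0.5/0.75; the other channels are exercised through explicit
arguments.

What the simulator does *not* emulate: biological between-patient
variation beyond i.i.d. noise, within-patient tumor/normal correlation,
count-depth-dependent variance (all samples share one noise sd), isoforms,
or sequence features. Passing recovery tests therefore demonstrates the
statistical machinery under the model's own assumptions, not performance
on real tissue data, where effect sizes are smaller and correlation
structure richer.

## Problem sizes used in testing

The test suite and `scripts/acceptance.R` run the full pipeline on the
preset scale (200 mRNAs × 60 miRNAs × 60 samples) — the scale at which the
whole stack, including a 200-fit mechanistic pass, completes in seconds —
with 20 replicate seeds for recovery and null-calibration summaries and
5 replicates in the acceptance script. Oracle checks (BH step-up, TMM
transcription, soft-thresholding, OLS, exhaustive correlation screening)
use small instances where brute force is exact.

## Known limitations

- **Support overselection bounds pair precision.** Under the `cv_min` rule
  the lasso keeps every predictor that lowers cross-validated error, and in
  a diseased cohort *all* shifted miRNAs are mutually correlated through
  the tumor indicator; each support therefore contains the true regulators
  (support recall is essentially perfect in the bundled presets) plus
  correlated extras, and since an emitted η drags its whole support into
  the pair list, pair precision saturates well below 1 even when recall is
  near 1 — `scripts/acceptance.R` recomputes both. `cv_1se` trades some of
  this for sparser supports. This mirrors the emission rule's own caveat:
  some miRNAs attached to a selected η may not be individually relevant.
- **Collinear linear predictors.** η columns of co-regulated mRNAs are
  highly correlated; the clinical lasso may keep one representative and
  drop the rest, costing recall at the mRNA level.
- **Independence assumption.** With strongly dependent tumor/normal pairs
  (high dependence-diagnostic correlations) the unpaired logistic model is
  mis-specified; the diagnostic is reported but not acted on.
- The correlation baseline is a plain Pearson screen, an approximation of
  component-based canonical-correlation comparators.
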