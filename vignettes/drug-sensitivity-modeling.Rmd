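---
title: "Modeling drug sensitivity from cell-line panels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling drug sensitivity from cell-line panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`drugresp` builds a drug-sensitivity signature from a cell-line screen and
carries it to patients on a different expression platform. This vignette
explains the model, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the procedure left room.

## The model and its assumptions

The response model is a 2-component PLS1 regression of log2(IC50) on
autoscaled log2 expression. PLS is a sensible default here because the
number of candidate genes far exceeds the number of cell lines, predictors
are strongly collinear (co-regulated genes), and the latent components seek
covariance with the response rather than raw predictor variance. The
framework's assumptions, in decreasing order of importance:

* **A monotone, roughly linear link** between (log2) expression of a
  limited set of genes and log2(IC50). Threshold or epistatic response
  mechanisms are outside the model class.
* **Transferable expression ranks.** Cross-platform translation assumes
  that, after best-match probe mapping and quantile normalization against
  the training panel, a patient sample's expression ranks are comparable to
  a cell line's. Systematic tumor-vs-cell-line biology (stroma, immune
  infiltrate) is *not* corrected.
* **A meaningful sensitive/resistant dichotomy** of the score
  distribution — the median for normal-like IC50 distributions, the density
  valley for bimodal ones.

The signature itself is not the fit of one model but the consensus of many:
the balanced/random split ensemble exists to privilege genes whose
association with response is stable across subsamples of a heterogeneous
pan-cancer panel, which is what gives the signature a chance to survive the
trip to patient data.

## Stage parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `keep_fraction` | 0.40 | fraction of features kept by mean intensity |
| `min_variance` | 1.0 | minimum sample variance, (log2)² |
| `p_cutoff` | 0.01 | raw permutation p gate for features |
| `n_perm` | 1000 | response permutations per feature test |
| `n_outer` × `n_inner` | 150 × 1000 | split ensemble size |
| `top_sets` | 5 | outer sets contributing representative models |
| `overlap_q` | 0.90 | null quantile for Jaccard overlap filtering |
| `start`, `eps`, `window` | 5, 0.005, 10 | forward selection: first size, flatness threshold, look-ahead |
| `delta` | 0.02 | non-inferiority slack of balance- vs random-validation medians |
| `pathway_p_cutoff` | 0.01 | hypergeometric enrichment gate |
| `n_components` | 2 | PLS components (components 1–2 define gene weights) |

The intensity/variance/p-value/pathway constants and the ensemble geometry
(70/30 outer, 60/40 inner, five top sets, 90% overlap quantile, start at
five genes) are the procedure's published constants. The quantitative forms
of the set-selection criteria are deliberately explicit and configurable:
`delta` and the plateau pair (`eps`, `window`) operationalize what the
method's authors judged visually from performance-curve plots. The ensemble
size is a compute dial, not a statistical one: simulated studies in this
package use 10 × 100 (tests, acceptance script) which is ample at n = 200;
real panels warrant the full 150 × 1000.

A note on "loadings": gene weights are `sqrt(PLS1² + PLS2²)` of the
*projection loadings* **P**. Some PLS implementations (e.g. mixOmics)
report the NIPALS weight vectors **W** under the name `loadings`; the two
coincide only for the first component's direction. Tests pin our fits to an
independent score-space NIPALS oracle and to mixOmics predictions.

## What the generator emulates — and what it does not

`simulate_panel()` draws per-gene baselines N(7, 1.5) with per-gene residual
SD in [0.6, 1.4]; a configurable number of driver genes carry a latent
sensitivity factor, and log2(IC50) is the signed, weighted sum of centered
driver expression plus N(0, `noise_sd`) noise. Two structural choices:

* **Drivers are well-expressed** (baseline N(9, 0.8)). The intensity filter
  exists to drop unexpressed features; a generator that scattered drivers
  uniformly over the intensity range would have the 40% cutoff delete true
  drivers for reasons that say nothing about the method.
* **Drivers form co-expression modules** (`driver_module_size`, default 5),
  each module sharing its own latent factor. One panel-wide factor would
  make every driver informationally redundant — five genes would carry all
  the signal, forward selection would (correctly) stop there, and consensus
  weighting would have nothing to distinguish. Disjoint co-regulated
  modules are closer to real pathway structure and give each driver
  marginal predictive value.

Bimodal panels place the shared mixture shift on every module factor so the
two IC50 mode centers sit exactly `bimodal_gap` apart; the generating
subpopulation label is kept as ground truth. Clinical cohorts are fresh
draws from the same generative model with an additive `platform_shift`,
renamed features (`P2_*`) behind a generated best-match table, and
exponential PFS with log-hazard `pfs_link` per standardized true score
(positive `pfs_link`: resistant progresses sooner; censoring is an
independent uniform administrative mechanism at rate `censor_rate`).
Dose-response curves are Hill curves over a 10-dose 3-fold dilution with
planted QC violations and a truth column.

What this deliberately does **not** emulate: probe-level noise and RMA
artifacts, tumor-vs-line biology (passing tests show the *pipeline*
recovers planted structure through a platform shift, not that cell lines
predict tumors), correlated or informative censoring, copy-number/mutation
structure beyond an optional binary event table, and batch effects beyond a
global additive shift.

## Numerical choices and degenerate inputs

* **Ties.** Intensity filtering and probeset collapsing break ties by
  higher variance then lexical feature id; balanced splits break rank ties
  by sample id; representative selection by higher balance-validation AUC
  then lower inner index. Everything downstream of a seed is deterministic.
* **Boundaries.** A score exactly at a cutoff is resistant; a PFS exactly
  at the responder cutoff is a responder. Confusion ratios with zero
  denominators are `NA`, never 0.
* **Quantile normalization** targets per-rank means of the reference; tied
  test values receive the mean of the straddling reference values; unequal
  feature counts interpolate the reference distribution linearly.
* **Fisher transform** inputs are clipped to 1 − 1e−12 in absolute value
  before `atanh`; zero-variance genes, constant event rows and single-class
  validation sets are excluded with messages rather than propagating NaN.
* **Valley cutoffs** use a Gaussian KDE with Silverman's bandwidth; the
  valley is the density minimum between the two highest modes, accepted
  only if the minor side holds ≥ 10% of observations — finite normal
  samples always show tiny spurious KDE modes, so a strict unimodality test
  would never fire.
* **NIPALS** stops early if a component's score norm falls below 1e−12
  (response variance exhausted); zero-variance columns are dropped before
  scaling. With full components on a full-rank problem the fit reproduces
  least squares, which the tests assert.
* **Seeds** fan out from one master integer through a
  multiplicative-congruential counter, so any single split of the ensemble
  is reconstructible from `(seed, outer_index, inner_index)` without
  storing 150,000 models.

## Open design points, resolved

* **Middle-tertile removal** is applied automatically only to panels
  declared `normal_like`, where the middle of the distribution carries the
  least class information; bimodal panels keep all lines.
* **The inner 60/40 split is unstratified** — the outer split already
  guarantees tertile representation on both sides of the fence that
  matters (training vs balance validation).
* **Consensus SVD runs on combined weights** `sqrt(PLS1²+PLS2²)` rather
  than per-component loadings: per-component SVD would need a component
  alignment step across models (components are sign- and
  rotation-unstable), while the combined weight is invariant to both.
* **Overlap filtering is rank-greedy** (keep the better-ranked model of an
  overlapping pair): deterministic and biased toward performance.
* **Two-sided feature p-values**, since both correlation signs are kept
  (sensitivity- and resistance-specific genes).
* **Evaluation accuracy on simulated cohorts** is reported against the
  generator's ground-truth sensitivity label. At these cohort sizes,
  dichotomized exponential PFS is mostly survival noise — the package
  computes and reports the PFS confusion block and the Cox/log-rank
  analysis, but calibration claims about the *classifier* are anchored to
  the label the simulation actually planted.

## Problem sizes used by the shipped analyses

The test suite and `scripts/acceptance.R` run the reference simulation at
2,000 genes / 30 drivers / 200 cell lines with a 10 × 100 ensemble, the
two-drug specificity study at 600 genes / 12 drivers / 150 lines / 150
patients with a 6 × 60 ensemble, and null-calibration studies at 60–100
samples with 300–1000 permutations. These sizes were chosen so the whole
evidence chain re-runs in minutes on a laptop while keeping every
statistical check comfortably powered.

## Known limitations

* PLSR components are fit without internal sparsity; very small panels with
  huge feature sets rely entirely on the permutation gate for variance
  control.
* The permutation p-value rests on a normal fit to the permuted
  Fisher-transformed correlations; heavy-tailed expression can make the
  tails of that fit optimistic (the null-calibration tests bound this at
  the simulated conditions, not universally).
* Cross-platform translation handles location/scale distortion; probe-level
  affinity differences that reorder samples within a gene are invisible to
  quantile normalization.
* The Cox model is univariate by design — no covariate adjustment — and
  uses Breslow tie handling.
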