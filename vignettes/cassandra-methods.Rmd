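---
title: "Cassandra lymph-node scoring: models, calibration and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cassandra lymph-node scoring: models, calibration and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cassandra)
```

## The scoring model

A resected axillary lymph node is described by eight ultrasound /
shear-wave-elastography features, each oriented so that *larger means more
suspicious*: stiffness (SWEH, kPa), the negated roundness index (−RI; round
nodes, i.e. low longitudinal/transverse ratio, are suspicious), cortical
thickness (CT, mm), and five 0/1 findings — loss of fatty hilum (LFH),
indefinite margins (UM), marked hypoechogenicity (Hy), peripheral
infiltration (PI) and peripheral vascularization (PV).

The three continuous features are dichotomized by a strict rule
`value > cut`; the Lymph Node Malignity Score is then an integer-weighted
sum of six binaries. Stiffness and roundness, the two strongest univariate
predictors, carry weight 2, the rest weight 1:

* **Model A** — cuts 142 kPa / −1.55 / 3.50 mm (per-feature Youden optima);
  call malignant if the score exceeds 3.50; range 0–8.
* **Model B** — cuts 137 kPa / −2.25 / 3.50 mm, chosen to keep per-feature
  sensitivity ≥ 0.95 (false negatives are the clinically expensive error);
  score cut 4.50.
* **Model C** — Model B without the stiffness term, for ultrasound machines
  without elastography; score cut 2.50; range 0–6.
* **Two-tier rule** — if the Model B binarizations of stiffness and
  roundness agree, call immediately (both suspicious → malignant, both not →
  benign); only discordant nodes are scored with Model B.

PI and PV are excluded from every score: in training-set screening their
AUC fails the retention test (p ≥ 0.001 under the Hanley–McNeil normal
test of AUC = 0.5). PI is nonetheless reported separately because it is a
rare, near-pathognomonic finding: an infiltrating node is essentially
always malignant, so the single-feature rule "PI ⇒ malignant" has a PPV of
100% even though its sensitivity is useless.

Exhaustive enumeration of all 2^6 binary inputs shows the only possible
disagreement between the two-tier rule and plain Model B: a tier-1
double-positive whose full score is exactly 4 (2 + 2 + nothing else) is
called malignant by the tier-1 shortcut but benign by the 4.50 cut. This
is by design — the tier-1 call deliberately trusts the two strong features
alone — and the test suite asserts the characterization exactly.

### Tier-1 roundness threshold

Two variants of the tier-1 roundness test are in circulation: the Model B
binarization (RI < 2.25) and a stricter RI < 1.55. The package defaults to
the Model B binarization, which makes tier 1 literally "the two Model B
binaries agree"; the stricter variant is available via
`model_spec("two_tier", tier1_ri_cut = -1.55)`. We default to the
methods-level definition rather than the stricter summary-level one
because it keeps the two-tier rule a pure function of the Model B
binarization.

## Evaluation statistics and numerical conventions

* **ROC/AUC** — tie-aware midrank formulation; identical to the all-pairs
  probability (malignant outscores benign, ties half). SE by Hanley–McNeil,
  the standard choice in clinical ROC software; the AUC p-value is the
  normal test of AUC = 0.5 on that SE. Gini = 2·AUC − 1 is enforced as an
  identity, and the maximum K-S statistic equals Youden's J at the optimal
  cut (both are asserted property-style in the tests).
* **Threshold reporting** — a selected cut is the midpoint between the two
  adjacent observed values, which yields half-integer score cuts (3.50,
  4.50, 2.50) and x.5 cuts for integer-valued kPa/mm data;
  `round_cut_to_int` floors to the whole unit to mimic clinically printed
  cut-offs. Classification is always strict (`> cut`), so ties fall on the
  non-suspicious side; published cuts sit between achievable values, making
  ties impossible in practice.
* **Youden ties** — equal J is broken toward higher sensitivity, then the
  lower cut, consistent with the sensitivity-first design of Model B.
* **Mann–Whitney** — U with midranks, z from the tie-corrected variance, no
  continuity correction (z values of order 10 make it irrelevant),
  two-sided p. Feature significance is gated at the Bonferroni level
  α = 0.006.
* **LDA** — pooled within-group covariance (divisor n − 2), group-size
  priors; standardized canonical coefficients are the raw discriminant
  direction scaled by pooled within-group SDs; the canonical correlation
  comes from the between/within generalized eigenvalue (and equals the
  Pearson correlation between discriminant score and label, which the
  tests use as an independent identity). A ridge of 1e−8 · trace/p is
  added only if the pooled matrix is numerically singular.
* **Naive Bayes** — Gaussian margins for the continuous features, Bernoulli
  with +0.5 pseudo-count smoothing for binaries (the only mixed-type
  formulation that fits covariates-plus-factors data). Predictor selection
  is greedy forward on training accuracy, candidates ranked by training
  AUC; `selection = "all"` disables it. Greedy selection by training
  accuracy *can* admit a noise feature through overfitting, so the test
  suite asserts the defensible property (the selected subset is never
  worse than the best single feature) rather than a no-noise guarantee.
* **Degenerate inputs** — rates with empty denominators (e.g. PPV with no
  positive calls) are reported as `NA`, never 0/0; constant features
  produce flagged-missing correlations; one-class inputs to ROC or cut-off
  search are errors, not silent 0.5s.

## The synthetic cohort generator

No per-node dataset is publicly deposited, so the package ships a
generator that emulates the published cohort structure: 529 nodes (320
benign, 209 malignant) with group-conditional marginals (means, SDs,
ranges, prevalences) and a shared pooled within-groups correlation
structure. Everything downstream — calibration policies, model evaluation,
baselines, the acceptance script — runs on these cohorts.

**Margins.** Continuous features are truncated normals on their published
ranges, rounded to the measurement grid (1 kPa for stiffness, 1 mm for
cortical thickness, 0.1 for the roundness ratio — grids chosen to match the
integer-valued published medians). The published mean/SD are treated as
*post*-truncation moments: an inner moment-matching loop solves for the
pre-truncation (μ, σ) such that the discretized, truncated margin
reproduces them. One margin deserves note: the malignant roundness target
(mean −1.35, SD 0.34 on [−2.8, −1.0]) sits essentially on the boundary of
the truncated-normal family, at the tilted-exponential limit where mass
piles against the upper range limit. The solver's best member matches the
mean to 0.006 and the SD to 0.008 — both inside three Monte-Carlo standard
errors at the scales the package simulates, which is the tolerance the
recovery tests use. Binary features are thresholded latent normals at the
prevalence quantile; the benign PI prevalence is exactly 0 (the published
table shows mean 0, SD 0; its "0–1" range cell is read as a formatting
artifact), so benign PI is degenerate and the PI ⇒ malignant rule has PPV
100% by construction on every generated cohort.

**Dependence.** A single latent correlation matrix is shared by both
groups — the target matrix is itself pooled within groups, so no
group-specific information exists to encode. Dichotomization and
truncation attenuate correlations, so each latent entry is found by
numerically inverting the map latent ρ → observed pooled within-groups
correlation. The forward map is computed by quadrature (Gauss–Hermite for
continuous margins, adaptive integration of the conditional normal CDF for
binary ones) under each group's margins, pooled with the LDA weights
(n_g − 1)/(n − 2). Unattainable targets (beyond the Fréchet bound for the
pair's margins) raise an error naming the pair. The assembled matrix is
repaired to positive semi-definiteness by eigenvalue clipping with
rescaling to unit diagonal; the maximum absolute adjustment is recorded on
the config (zero for the default targets). With heteroscedastic groups the
pooled correlation is strictly below each group's own correlation
(Cauchy–Schwarz on the pooled covariance), so calibrated latent values
exceed their targets even for two continuous features; the identity
latent = target holds only in the homoscedastic untruncated case, which is
what the corresponding test checks.

**What the generator does and does not emulate.** Twenty-seed cohorts
recover the target means/SDs within three Monte-Carlo SEs and the pooled
correlations within ±0.08 entrywise (the acceptance tests assert both, and
the acceptance script reports the recovered Hy–PV and SWEH–LFH entries).
It does *not* model within-patient clustering of nodes (no such structure
is published; `patient_id` is synthetic bookkeeping), nor the exact joint
distribution behind the published model accuracies or the 44% tier-1
fraction — marginals plus a pooled correlation matrix underdetermine those
quantities, and on these cohorts the tier-1 fraction comes out near 65%.
Consequently, passing tests show the *machinery* is right (score algebra,
calibration policies, orderings such as Model B's sensitivity dominating
Model A's, and AUCs above 0.9 for all models), not that real-cohort
accuracy figures are reproduced. Published whole-sample descriptives that
are mutually inconsistent with the group-wise table (e.g. a whole-sample
CT SD smaller than either group's) are ignored in favor of the group-wise
table.

## Problem sizes

The package's own test and reporting scales: single cohorts of 529 nodes;
20-seed replicates for recovery statistics; 10,000-node cohorts (group
sizes scaled proportionally) for the large-sample check that the Youden
cut for stiffness converges to the analytic density crossing of the two
group margins (within 2 kPa); 100-instance randomized batches for the
metric identities. A full `run_full_study()` on 529 nodes, including the
LDA leave-one-out loop, takes about a second.

## Known limitations

* Cut-off search enumerates midpoints of observed values — appropriate for
  gridded clinical measurements, O(n·u) in the number of unique values.
* The naive Bayes selection criterion (training accuracy) is the simplest
  defensible reading of "selects the best predictors"; alternative
  criteria (AIC, cross-validated accuracy) would change the selected set
  on small cohorts.
* The generator's latent-normal dependence cannot represent all joint
  distributions of mixed margins; tail dependence in particular is fixed
  by the copula choice.
* `split_cohort()` splits by node; splitting by patient is not meaningful
  for the synthetic cohorts because no within-patient structure is
  generated.
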