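---
title: "Methods: the IBR index and factorial ANOVA workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the IBR index and factorial ANOVA workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibrtox)
library(dplyr)
```

`ibrtox` analyses oxidative-stress biomarker batteries from crossed
multi-stressor exposure designs. This vignette explains the statistical
model behind every stage, the parameters that matter, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## The data model

A *battery* is a long table with one measured value per record, keyed by
treatment (water temperature in °C crossed with toxicant cell density in
cells/mL), sampling day, replicate tank, and biomarker name. Replicates
are tanks, not repeated measures on individuals: animals are sampled
destructively at each time point, so sampling days are treated as
independent groups throughout (day-wise post hoc letters, a fixed `day`
factor in the ANOVA). Biomarker activities are ratio-scale positive
quantities; strict positivity is enforced because the IBR's first step is
a log-ratio.

The canonical design bundled as `design_spec()` is 3 temperatures
(20/25/30 °C) × 3 densities (0, 10⁵, 10⁶ cells/mL) × 4 days (1/3/5/7) × 3
replicate tanks — 108 observations per biomarker, 756 for the
seven-biomarker battery.

## The IBR index

For one biomarker within one standardization scope (by default, one
sampling day), with treatment means $X_i$ and reference-treatment mean
$X_0$:

$$Y_i = \log_{10}(X_i / X_0), \qquad
  Z_i = \frac{Y_i - \mu}{\sigma}, \qquad
  A_i = Z_i - Z_0, \qquad
  \mathrm{IBR} = \sum_i |A_i|.$$

Choices that the literature leaves open, and how this package resolves
them:

* **Aggregation.** Some formulations sum the signed deviations, which
  lets an induced biomarker cancel an inhibited one (e.g. GR suppression
  against SOD induction). The default here is the IBRv2 convention
  $\sum |A|$; `ibr_options(aggregation = "signed_sum")` gives the signed
  variant. The invariant $\sum|A| \ge |\sum A|$ is asserted in the tests.
* **Standardization scope.** Day-wise star plots imply day-wise $\mu,
  \sigma$; that is the default (`scope = "within_day"`). Pooling across
  days (`"across_days"`) is available for sensitivity analysis.
* **Reference treatment.** The unexposed group at the lowest temperature,
  configurable via `ibr_options(reference = ...)`. The reference scores
  exactly 0 under both aggregations — a structural identity, not a
  numerical accident.
* **$X_i$ is the treatment mean** over replicate tanks; the index carries
  no replicate subscript, and replicate-level IBR is out of scope.
* **$\sigma$ uses the $n-1$ denominator** (sample SD over the treatments
  in scope).
* **Log base.** Base 10 by convention. Changing the base rescales every
  $Y_i$ by the same positive constant, which the standardization removes:
  $Z$, $A$ and the IBR are base-invariant, and so are they under any
  units change of a single biomarker (the constant cancels inside the
  log-ratio). Both invariances are asserted in the tests, which is why
  the base choice is immaterial.
* **Degenerate scope.** If a biomarker's log-ratios are identical across
  all treatments in a scope (σ = 0 — it did not respond at all), the
  biomarker contributes $A = 0$ rather than an undefined 0/0. The
  low-level `ibr_standardize()` keeps the strict error so that the
  degenerate case cannot pass silently through user code.

`star_coordinates()` places the biomarkers at fixed angles $2\pi k/m$ in
the battery's declared order with the *signed* $A$ as radius, so induced
and inhibited biomarkers are visually distinct even under the
absolute-sum index.

## Three-way ANOVA

`fit_three_way_anova()` implements the classical balanced decomposition
directly: main-effect sums of squares from marginal means, two-way
interaction SS from two-way cell means with main effects removed,
three-way SS by inclusion–exclusion, error SS within cells. With a
balanced design, Type I/II/III sums of squares coincide, so no SS-type
choice arises; unbalanced input is a hard error naming the first
deficient cell, never a silent fallback. All factors are fixed effects
and replicate tanks form the single residual stratum; each term is tested
against the residual mean square with `f_upper_tail()`, the regularized
incomplete beta identity for the F upper tail. A constant response yields
zero SS everywhere and flagged (`NA`) F statistics.

The test suite checks this implementation against `stats::aov` on
hundreds of random balanced designs to 1e-8 relative tolerance; `aov` is
an oracle there, never the implementation.

### Tukey HSD and letters

Pairwise treatment comparisons are done day-wise (matching letters
reported "among treatment groups at each sampling time"): the error mean
square comes from a one-way ANOVA on that day's 9 groups (`error_stratum
= "within_day"`, df = 18 in the canonical design), with the three-way
residual stratum (df = 72) available as an option. For each pair,
$q = |\bar x_i - \bar x_j| / \sqrt{MS_e/n}$, and the adjusted p-value is
the studentized-range upper tail.

`studentized_range_upper_tail()` evaluates the distribution by direct
double numerical integration — the inner integral over the location of
the extreme mean, the outer over the scale estimate
$s = \sqrt{\chi^2_\nu/\nu}$ — using composite Gauss–Legendre panels
(24-point panels over the scale, trimmed to 1e-12 tail mass; 12-point
unit-width panels over a location range of 8.5 normal SDs, beyond which
the integrand's normal-density factor vanishes). These node counts hold the absolute error
below 1e-6 across the (k, df) combinations that arise here, which is
ample for stable letter assignments; at k = 2 the tail reduces to
$2(1 - F_t(q/\sqrt 2; \nu))$, a closed-form check the tests enforce.

`compact_letter_display()` uses the insert-and-absorb algorithm. Its
guarantee is exact sharing: two groups share at least one letter *iff*
their adjusted p-value is at or above α. The letter set is not guaranteed
minimal (a known property of the algorithm); letters are ordered so that
"a" labels the set containing the largest group mean.

### Assumption checks

`levene_test()` is the classical mean-centered Levene: a one-way F on
absolute deviations from group means, with the all-constant case mapped
to W = 0, p = 1. `pearson_matrix()` pairs observations across biomarkers
by full key and errors on zero-variance biomarkers.

## PCA

`build_condition_matrix()` collapses replicates to condition means — 36
rows (9 treatments × 4 days) by 7 biomarker columns in the canonical
design, condition-level rather than replicate-level because ordination
scores are reported per condition — then z-scores each column.
`biomarker_pca()` takes the SVD of that matrix, which is a
correlation-matrix PCA: the right choice when variables carry
incommensurable units. Loadings are orthonormal, explained-variance
shares are non-increasing and sum to 100 % over all components, and each
loading column is oriented so its largest-magnitude entry is positive —
the orientation of a principal axis is arbitrary, and a deterministic
convention keeps runs and tests reproducible.

## The synthetic generator

`generate_battery()` draws each record from a log-linear mean model with
multiplicative lognormal noise. With 0-based level ranks $t, d, y$:

$$\mathbb{E}_0 = B \exp(\beta_T t + \beta_D d + \gamma\, t d + \beta_Y y),
\qquad \text{value} = \mathbb{E}_0 \cdot e^{\sigma Z},\; Z \sim N(0,1),$$

with $\sigma = \sqrt{\ln(1 + cv^2)}$ so `noise_cv` is the coefficient of
variation of the noise. Effects are linear in level *rank* rather than
physical units because typical dose series (0, 10⁵, 10⁶ cells/mL) are
log-spaced with a zero — rank coding is the only uniform choice.
Multiplicative noise keeps values positive (the log-ratio is always
defined) and reflects how assay variability scales with activity level.
One RNG stream is advanced in a fixed record order (biomarker outermost,
replicate innermost), so identical configurations are byte-identical and
appending a biomarker last leaves earlier draws unchanged; the caller's
RNG state is saved and restored.

`clam_preset()` encodes the emulated study conditions:

| parameter | default | rationale |
|---|---|---|
| baselines | GST 40, SOD 60, CAT 15, GPx 30, GR 8 U/mg prot; ROS 100 a.u.; MDA 5 nmol/mg prot | plausible control magnitudes for bivalve hepatopancreas assays |
| `dose_slope` | +0.30 to +0.35 (GR: −0.25) | toxicant exposure induces the battery; GR activity is suppressed |
| `temp_slope` | +0.15 to +0.20 | warming elevates metabolic and oxidative load |
| `interaction_strength` | 0.12 | a moderate thermal–toxicant synergy (≈1.6× multiplicative at the extreme cell); at the design size it gives the interaction F test near-certain detection (noncentrality λ = 48γ²/σ² ≈ 31) |
| `time_slope` | 0 | responses in one-week exposures of this kind are stable across days |
| `noise_cv` | 0.15 | a typical between-tank CV for biochemical assays; no published variance estimates exist for calibration, so this is a stated assumption |

**Calibration studies fit the ANOVA on the log scale.** The generator's
effects are multiplicative, so even with γ = 0 the *raw-scale*
temperature × density interaction is nonzero (a product of main effects
is not additive). On the log scale the model is exactly additive, the
null is exact, and the interaction p-value is uniform — which the
calibration tests verify over 1000 simulated studies (type-I rate inside
the exact binomial 99 % band around 0.05, Kolmogorov–Smirnov uniformity).
User-facing fits default to the raw response, which is how such data are
conventionally analysed.

What the generator does *not* emulate: toxicokinetics (uptake/depuration
dynamics), between-biomarker residual correlation beyond what the shared
design induces, heavier-tailed or assay-specific error structures, and
tank effects distinct from residual noise. Passing calibration and power
checks therefore demonstrates correctness of the statistical machinery
under a clean multiplicative model — not that any particular field data
set satisfies those assumptions.

## Problem sizes and runtime choices

The simulation-based checks use 1000 seeds for null calibration, 200 for
interaction detection, 100 for IBR dose monotonicity, and 100 random
small designs (2–3 levels per factor, 2–3 replicates) for the ANOVA
oracle comparison — sizes at which binomial/KS assertions are sharp while
a full run stays in the low minutes on a single core.

## Limitations

* Unbalanced designs are rejected, not accommodated; there is no
  missing-data imputation.
* All factors are fixed; no mixed/random-effect or repeated-measures
  structure.
* The original triangular-area IBR variant and bootstrap confidence
  intervals for the index are not implemented.
* Normality testing is not included; Levene's test is the implemented
  assumption check.
* Compact letter displays are correct but not guaranteed minimal.
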