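---
title: "Profiling extracellular vesicles to discriminate resilience phenotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling extracellular vesicles to discriminate resilience phenotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evresilience)
```

## The analysis problem

Imaging flow cytometry (IFC) measures tens of quantitative image features
for every object it detects — size, shape, texture and signal-strength
descriptors per fluorescence channel. When the objects are extracellular
vesicles (EVs) stained for subpopulation markers (CD63 for exosome-sized
vesicles, VAMP3 for microvesicle-sized, THSD1 for apoptotic-body-sized),
each blood sample becomes a table of thousands of events by ~100 features.
The scientific question this package serves: can features of the circulating
EV profile — at baseline, or in their response to an acute stressor —
discriminate individuals with high trait resilience (resilience-scale score
> 90 of 100) from those with low trait resilience (score ≤ 79)?

The pipeline has four stages, each exposed as ordinary tibble-in /
tibble-out functions:

1. **Reduction** — collapse each per-event table to a fixed per-sample
   profile of 1116 variables.
2. **Selection** — down-select candidate variables with
   least-squared-deviation (LSD) regression trees fitted against the
   continuous resilience score.
3. **Comparison** — normality-routed two-group tests with Hedges' *g*
   effect sizes for the candidates.
4. **Diagnostic accuracy** — ROC curves, Youden-index cutoffs and positive
   likelihood ratios for the significant candidates.

Because no subject-level data are publicly available for this design, the
package includes a first-class synthetic cohort generator that emulates the
data structure the analysis assumes, so every stage is testable end to end.

## Reduction to the 1116-variable profile

Each sample's events are first cleaned: any object with a saturation count
≥ 1 in any fluorescence channel is removed as probable debris or
fluorochrome aggregate, and a derived feature, the pixel range
(raw max pixel − raw min pixel), is added per channel.

Events are then stratified by brightfield image area. The cutoffs are the
areas of circles of diameter 200 nm and 1000 nm — `pi * 0.1^2 = 0.031416`
and `pi * 0.5^2 = 0.785398` µm² — the conventional diameter boundaries
separating exosomes, microvesicles and apoptotic bodies. *Small* events
have area below the first cutoff, *medium* events lie between the cutoffs
(both boundaries inclusive), *large* events above the second; *total* is
the unstratified sample.

For every active feature × channel, the mean (AVG), median (MED) and
sample standard deviation (SD, n−1 denominator, the SPSS descriptive
convention) are computed in each of the four strata:

```
31 features × 3 channels × 4 strata × 3 statistics = 1116 variables,
372 per statistic: 96 size + 12 shape + 72 texture + 192 signal strength.
```

The default feature manifest reconstructs a 31-feature list (8 size, 1
shape, 6 texture, 16 signal-strength features) that reproduces those
printed category counts; vendor exports do not standardise which features
survive curation, so the manifest — including the three features excluded
as redundant and five as irrelevant, and an alias map for vendor column
spellings — is fully configurable. Per-channel variables are computed over
all retained events in that channel; an optional per-channel positivity
gate is available (default: no gate) because marker-positivity thresholds
are not standardised for this design.

Missingness is data, not an error: a stratum with no events has AVG and
MED missing, a stratum with fewer than two events has SD missing. Change
scores are the per-variable difference `D3 − D0` (peak stress minus
baseline), missing whenever either side is missing. Variables missing for
any subject are excluded listwise from tree fitting, which has no
surrogate splits.

## Regression-tree feature selection

The selector is a from-scratch CART-style regression tree for a continuous
outcome. A split on variable *x* at threshold *t* partitions a node; the
LSD criterion picks the (variable, threshold) pair that maximally reduces
the within-node sum of squared deviations of the outcome. Thresholds are
searched at midpoints between consecutive distinct values (standard CART).
The *risk estimate* of a fitted tree is the within-terminal-node variance
`(1/N) Σ_nodes Σ_i (y_i − ȳ_node)²`, reported also normalised by the
outcome's population variance, so a root-only tree scores exactly 1 and
pure leaves score 0.

Three stopping rules fit the small-cohort design (N = 20): at least 5
observations per terminal node, at least 10 before a node may split, and a
maximum depth of three levels. A fourth guard, a minimum normalised-risk
improvement of 10⁻⁴ per split, matches the common CRT default in
commercial statistics software. There is no pruning, no surrogate split
handling and no cross-validation — the tree is a deterministic variable
selector, not a predictive model.

Determinism is part of the contract: equal-improvement ties break to the
earliest variable in manifest order, then to the smaller threshold, and the
search runs on sorted values, so row order cannot change the tree. A
relative tolerance of 10⁻⁹ of the parent node's SSE absorbs float noise
when two algebraically identical partitions are reached along different
arithmetic paths.

Selection is two-level, run separately per statistic (AVG, MED, SD so that
location and dispersion signals are never conflated before the end): one
tree per feature category (size, shape, texture, signal strength) on that
category's variables, then a final tree on the union of the category
trees' splitter variables. The candidate set is the union of the three
final trees' splitters. "Splitters of a category tree" defaults to *all*
split variables of the tree (`level1_scope = "all_splitters"`); the
alternative reading — only the first-level (root) split — is available as
`level1_scope = "root_only"`. We default to all splitters because category
trees at these settings rarely contain more than three splits, and
forwarding only roots would often hand the final tree a single variable,
making the second level vacuous.

Selected-then-tested inference on the same 20 subjects is circular by
construction — the trees pick variables for their association with the
score that also defines the groups. The package mirrors that published
workflow rather than correcting it; the null-calibration tests therefore
check the *unselected* comparison at nominal α, and separately that the
null pipeline's candidate sets stay small.

## Group comparison and effect sizes

For each candidate, Shapiro–Wilk (α = 0.05, per group) routes to either
the pooled-variance Student *t*-test (both groups consistent with
normality) or the Mann–Whitney *U* test with an **exact** sampling
distribution for *U*. The exact null distribution is computed by the
standard dynamic-programming recursion
`c(m, n, u) = c(m−1, n, u−n) + c(m, n−1, u)`; with ties the mid-rank *U*
is referred to the fully enumerated permutation distribution (up to 16
subjects pooled), beyond that a tie-corrected normal approximation is used
and flagged. Two-sided p-values are twice the smaller tail, capped at 1.
Pooled-variance *t* (not Welch) is the default because the effect size is
defined against a pooled SD and it is the default primary row of the
software convention being mirrored; a Welch option is a one-line change in
`compare_groups()` callers via `stats::t.test` if ever needed.

Hedges' *g* applies the small-sample correction `J = 1 − 3/(4·df − 1)`
(df = n₁+n₂−2) to Cohen's *d* with pooled SD. With the height summaries
181.13 ± 5.76 versus 174.05 ± 6.67 (n = 10 per group) this yields
*g* = 1.09 — the package's worked example. The CI uses the normal
approximation `SE² = (n₁+n₂)/(n₁n₂) + g²/(2(n₁+n₂))`, which reproduces
published intervals for this design to within a few hundredths; the exact
CI method behind such published intervals is typically unstated, and we
standardise on this one and record it.

Paired stress-effect tests (biomarkers, NTA concentration/size) route the
within-subject differences through Shapiro–Wilk to a paired *t* or an
exact Wilcoxon signed-rank test (exact rank-sum distribution without ties;
full 2ⁿ sign enumeration with ties up to n = 16).

## Diagnostic accuracy

ROC curves are built over thresholds at midpoints between consecutive
distinct scores plus sentinels. Orientation is chosen automatically so the
AUC is ≥ 0.5 and is recorded as a rule direction (`">"` or `"<"` the
cutoff), since either direction can be the biologically sensible one. The
AUC equals the Mann–Whitney statistic `U/(n₁n₂)` — asserted as a
cross-module identity in the test suite. The AUC CI and the test against
AUC = 0.5 use the Hanley–McNeil standard error; the optimal cutoff
maximises the Youden index `J = sensitivity + specificity − 1` (ties
towards higher sensitivity, then the lower cutoff); sensitivity and
specificity carry Wilson score intervals; and the positive likelihood
ratio is `sens/(1 − spec)` (8.00 at the 80%/90% operating point, 2.25 at
90%/60%). Published intervals for sensitivity/specificity in this design
match Wilson at the lower bound but not exactly at the upper; we
standardise on plain Wilson and record the method in the output.

## The synthetic cohort generator

The generator is the package's test bed: it draws cohorts with the
statistical structure the analysis assumes, not an optical simulation of a
cytometer. Defaults encode the emulated study's conditions:

* **Cohort**: 10 high- + 10 low-resilience subjects; scores from
  truncated normals — high ~ N(94.90, 3.04) on (90, 100], low ~
  N(70.00, 5.89) on [0, 79]; 2,000–10,000 events per sample (uniform),
  desk-scale but enough for stable per-stratum SDs.
* **Areas**: a three-component lognormal mixture with weights
  (0.60, 0.30, 0.10) for small/medium/large, each component truncated to
  its stratum so the weights are exact occupancy probabilities (component
  medians 0.012, 0.15, 1.5 µm²).
* **Intensities**: lognormal per feature × channel with a subject-level
  random effect (SD 0.3) on the log-mean — strictly positive, right-skewed,
  with realistic between-sample heterogeneity. Raw max pixel = raw min
  pixel + a positive lognormal increment, so `RawMax ≥ RawMin ≥ 0` holds by
  construction; aspect ratios are Beta(4, 1.3) on (0, 1]; a fraction
  `p_sat = 0.02` of events receives a saturation count ≥ 1 in one channel.
* **Effects** are implanted at D3 only, per group, because the emulated
  design found group differences in change scores, not at baseline.
  Effect A scales the log-scale spread of THSD1 bright detail intensity
  among large events (factor 2.0 high group, 1.0 low), lighting up the
  change score of the `BrightDetailIntensity_THSD1_large_SD` variable.
  Effect B shifts a min-pixel feature among medium events additively
  (−2.0 in the high group). The default universe has the three antibody
  channels only — the printed 1116-variable count fixes that — so the
  "scatter-like" effect B is carried by a designated antibody channel
  (default VAMP3) rather than a separate scatter detector.
* **Biomarkers**: D0 lognormals moment-matched to each group's published
  baseline mean ± SD for α-Klotho, BDNF, NPY, IGF-I and cortisol; D3 is
  the subject's D0 value × (1 + decline) × mean-one lognormal noise
  (SD 0.1), with default declines −8.9%, 0, −17.2%, −13.5%, 0
  respectively — so D3 dispersions scale with the decline, a choice made
  because no D3 dispersions are published. The NTA panel is matched to
  the published concentration/size summaries with no implanted stress
  effect.

What the generator does **not** emulate: spectral spillover and
compensation artefacts, instrument drift, correlated features (all noise
features are independent given the subject effect), marker co-expression,
or non-lognormal heavy tails. Passing tests therefore demonstrate that the
*pipeline machinery* is correct and well calibrated under the assumed
structure — not that real EV data carry the implanted signal.

## Numerical choices and degenerate inputs

* SD uses n−1; IQRs use the weighted-average percentile method
  (`quantile(type = 6)`), matching the descriptive conventions of the
  software being mirrored.
* Boundary areas: both stratum cutoffs belong to the medium stratum.
* All-saturated samples, empty strata, constant variables, all-zero
  paired differences, single-valued ROC scores and perfect specificity
  all return flagged values (`NA`, p = 1, collapsed CI, `Inf`), never
  silent errors; truly unusable inputs (missing columns, non-numeric
  cells, `RawMax < RawMin`, both-class absence) fail loudly with the
  offending stage and column named.
* Reports are deterministic: identical configuration + seed + inputs give
  byte-identical output files; provenance records a config hash, the seed
  and the package version (deliberately no wall-clock timestamp, which
  would break byte-identity).

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything from code:
tree-oracle sweeps use ≥ 1000 random instances at n ≤ 12 with ≤ 3
variables; exact-test oracles enumerate all labelings up to 12 pooled
subjects; null calibration uses 1000 simulated 10 + 10 cohorts at the
subject level and 200 reduced cohorts (5 + 5 subjects, 100–200 events per
sample) through the full pipeline; implanted-effect recovery runs 50
(tests) / 25 (acceptance script) full cohorts at the default 2,000–10,000
events per sample. These sizes are the package's own choice of
desk-scale reproducibility; all are parameters, not constants.

## Known limitations

* The default feature list reconstructs the printed category counts; the
  actual curated feature list of any given laboratory template will
  differ. The manifest exists precisely so users encode theirs.
* Post-selection inference is mirrored, not corrected (no multiplicity
  adjustment, matching the emulated workflow); a config hook for
  `p.adjust` would be the natural extension.
* The Hedges-*g* CI and sensitivity/specificity CI methods are stated
  conventions, near but not identical to every published interval for
  this design.
* Exact tests fall back to flagged approximations beyond enumerable
  sizes (ties with > 16 pooled subjects; > 40 untied).
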