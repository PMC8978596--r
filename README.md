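# evresilience

Extracellular-vesicle (EV) feature profiling for resilience phenotyping
from imaging-flow-cytometry (IFC) exports.

## The problem

IFC instruments detect thousands of vesicle-sized objects per plasma
sample and export ~100 quantitative image features per object (size,
shape, texture, signal strength) across fluorescence channels. Given
samples stained for EV subpopulation markers (CD63, VAMP3, THSD1) at
baseline (D0) and at peak stress (D3), plus a continuous trait-resilience
score per subject (0–100; *high* > 90, *low* ≤ 79), the question is
whether any feature of the EV profile — or of its stress response
(change score D3 − D0) — discriminates high- from low-resilience
individuals, and how well.

`evresilience` implements that analysis end to end, for biostatisticians
and physiology researchers working with per-event IFC feature tables:

1. **Reduction** — saturation filtering, a derived per-channel pixel-range
   feature (raw max − raw min pixel), size stratification of events by
   brightfield area (*small* < 0.031416 µm² ≤ *medium* ≤ 0.785398 µm² <
   *large*, plus *total*), and per-sample summaries
   (mean / median / SD of every feature × channel × stratum):
   31 × 3 × 4 × 3 = **1116 variables per sample**
   (96/12/72/192 size/shape/texture/signal-strength variables per
   statistic).
2. **Selection** — from-scratch least-squared-deviation (CART-style)
   regression trees against the resilience score, with small-cohort
   stopping rules (≥ 5 per terminal node, ≥ 10 to split, depth ≤ 3) and
   SPSS-style normalised risk R/Var(y). Two levels per statistic: one
   tree per feature category, then a final tree on the union of their
   splitters; candidates are the union of the final trees' splitters.
3. **Comparison** — Shapiro–Wilk routing to a pooled-variance *t*-test or
   an exact Mann–Whitney *U* (dynamic-programming null distribution;
   permutation enumeration under ties), with Hedges'
   *g* = J·(m₁−m₂)/s_pooled, J = 1 − 3/(4df−1) for significant parametric
   contrasts, and paired *t* / exact Wilcoxon signed-rank stress-effect
   tests for biomarker and NTA panels.
4. **Diagnostic accuracy** — ROC curves with AUC = U/(n₁n₂),
   Hanley–McNeil CI and test vs 0.5, Youden-index optimal cutoff
   (J = sens + spec − 1) with Wilson CIs, and the positive likelihood
   ratio LR⁺ = sens/(1 − spec).

Because subject-level data for this design are not public, the package
ships a first-class synthetic cohort generator (`generate_cohort()`):
per-event tables with lognormal intensities, subject-level random
effects, a stratum-truncated area mixture, implantable group × timepoint
effects, and moment-matched biomarker/NTA panels — so the whole pipeline
is testable and demonstrable from code alone.

## Worked example

```r
library(evresilience)

cohort <- generate_cohort(seed = 42)  # 10 high + 10 low, D0 + D3 tables
report <- run_pipeline(pipeline_config(cohort = cohort, mode = "change", seed = 42))
report
#> <ev_report> modes: change; 20 subjects
#>   change: 8 candidate(s), 5 significant, 5 ROC analysis(es)

tidy(report$analyses$change$selection)[6, ]
#> # A tibble: 1 x 6
#>   variable_id                          feature               channel stratum statistic selected_by
#>   BrightDetailIntensity_THSD1_large_SD BrightDetailIntensity THSD1   large   SD        SD

dplyr::select(report$analyses$change$comparisons, variable_id, test, p, g)[6, ]
#> # A tibble: 1 x 4
#>   variable_id                          test      p            g
#>   BrightDetailIntensity_THSD1_large_SD student_t 0.000000140  3.56

dplyr::select(report$analyses$change$roc, variable_id, auc, cutoff, direction)[4, ]
#> # A tibble: 1 x 4
#>   variable_id                          auc   cutoff direction
#>   BrightDetailIntensity_THSD1_large_SD 1     38.7   >
```

Reading: the generator implants a doubling of the within-sample spread of
THSD1 bright detail intensity among large EVs at D3 in the high-resilience
group. The change-score selection workflow recovers exactly that variable
(`..._large_SD`) among its candidates; the group comparison routes to a
pooled *t*-test (p = 1.4 × 10⁻⁷, Hedges' g = 3.56), and its ROC rule
"change-score SD > 38.7 calls high resilience" separates the groups
perfectly on this synthetic cohort (AUC = 1). `autoplot()` on a
`roc_curve()` result draws the curve with the Youden point marked.

A thin command-line wrapper with `simulate` / `reduce` / `select` /
`compare` / `roc` / `run` subcommands is installed at
`inst/scripts/ev-pipeline.R`.

## Vignette

`vignettes/ev-resilience-methods.Rmd` documents the model and its
assumptions, the default parameters and why, what the synthetic generator
does and does not emulate, numerical conventions, and known limitations.
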