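---
title: "Detection-pattern analysis of longitudinal presence/absence exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection-pattern analysis of longitudinal presence/absence exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detpat)
```

## The model and its assumptions

`detpat` relates longitudinal binary exposure histories — detection or
non-detection of microbial taxa in infant fecal samples at days 4, 10, 30
and 120 — to a continuous growth outcome, the change in weight-for-age
Z-score between birth and roughly six months (ΔZ). A child growing along
its birth percentile has ΔZ = 0; the conventional half-width for "expected
growth" is |ΔZ| ≤ 0.67, and that constant is the package's default
equivalence margin δ.

Both analyses assume ΔZ is approximately Normal within exposure groups,
subjects are independent, and strata (here the sexes) are analysed as
fully separate procedures — separate testable-pattern filtering, testing
and error control — because effect modification by the stratum is the
reason to stratify in the first place. Consequently every error-rate
guarantee in this package is *per stratified analysis*; this matters for
how the simulation harness tallies false discoveries (below).

### Time-specific analysis

For taxon *j* at day *t* the outcome is regressed on the 0/1 detection
indicator. With a binary regressor, ordinary least squares is exactly the
difference of group means with the pooled-variance standard error, and the
implementation computes that closed form (it is verified against `lm()`
and the pooled *t* test in the test suite). The J taxa form families; the
estimable days within a taxon are that family's components. Families are
summarised by Bonferroni pooling (p̃ = m·min p), screened across taxa by
Benjamini–Hochberg at level α, and, with R families rejected, components
are tested at α\* = Rα/(n·m_j). The analysis is run at α = 0.05 and again
at a relaxed 0.20 to flag suggestive effects; the strict rejections are
always a subset of the relaxed ones.

Two decisions here were genuinely open. First, a day on which detection
is constant (everyone or no one detected) yields no estimable effect; it
*shrinks the family* (m_j decreases) instead of entering as p = 1, because
a phantom component only inflates the Bonferroni factor without carrying
information. Second, the component-level formula α\* = Rα/(n·m_j) is
stated per family so that unequal family sizes are handled; with equal
families it reduces to the usual symmetric form.

### Pattern analysis

A *pattern* assigns `+` (detected), `-` (non-detected) or `X` (irrelevant)
to each day, with `X` confined to a right-hand suffix. All 2^T full
patterns are enumerated (16 at T = 4). For each taxon, patterns observed
in at least 15% of the analysable subjects are *testable*; below that
frequency a group of ~100 subjects leaves too few members to power an
equivalence test. The boundary is inclusive — exactly 15% is testable —
reading the exclusion rule ("less frequent than the floor is dropped")
literally. The frequency denominator is the set of subjects analysable
for that taxon in that stratum: complete detection data at all T days
*and* a non-missing outcome. Complete cases are required because a
four-day pattern is simply undefined for a subject missing a day, and a
subject without an outcome cannot contribute to a group mean.

Each testable group's mean is tested for equivalence to zero within δ by
the intersection–union of two one-sided tests,

p = max{ P(T_{n−1} ≤ (μ̂ − δ)/se), P(T_{n−1} ≥ (μ̂ + δ)/se) },

small p supporting equivalence (expected growth). Student's *t* with the
group's own n − 1 degrees of freedom and its own standard error is used —
groups can be as small as ~15 subjects, a Normal reference would be
anti-conservative, and pooling variances across patterns would couple
hypotheses that the mdFDR structure treats as separate components.

The mdFDR controller then runs with taxa as families and testable
patterns as components, exactly as in the time-specific analysis.

### Sequential right-side reduction

A rejected four-day pattern may carry superfluous trailing days. The
cascade starts at the component level L = α\*: if the current pattern's
p ≤ L/2, half the level is banked to preserve the standing rejection and
the right-reduced pattern is tested at the other half; on success the
reduced pattern becomes current at level L/2 and the cascade continues,
otherwise it stops (also at a single remaining relevant day). Reduction
is right-side only: a later exposure cannot cause an earlier one, so
right-truncation relaxes the hypothesis without opening a confounding
path. The *equal* halving of each level into "keep" and "continue" halves
is a design choice — any split summing to L preserves the guarantee, and
the symmetric split is the only one that privileges neither stopping nor
continuing. The cascade is deliberately isolated in
`sequential_reduction()` so an alternative allocation can be swapped in
one place. Its two defining invariants — the entry rejection is never
revoked, and levels halve at every step — are property-tested.

### Post-hoc screening

A pattern "significantly close to zero" is only interesting if deviating
from it is harmful. The screen therefore tests the final pattern's crude
contrast (all relevant symbols flipped) for difference from zero at 0.05;
a non-significant or inconclusive (n < 2, or degenerate) contrast
discards the finding from the significant-findings report (it remains in
the audit table). A significant contrast triggers a Welch comparison of
the pattern and contrast groups, at a relaxed 0.10 because only the two
groups' subjects enter this test; Welch results at or below 0.05 are
tiered "strict". The two screening levels are configurable
(`analysis_config()`); 0.05/0.10 are the package defaults, with the Welch
level deliberately the looser of the two. The screen compares the groups
of the *final reduced* pattern, not the original four-day pattern — the
reduced pattern is the reported finding, so its contrast is the relevant
comparison population.

## The synthetic-cohort generator

`simulation_config()` describes the cohort structure the method was built
for, and its defaults are the package's reference conditions:

* two strata of 110 and 108 subjects (the 218-infant scale);
* 22 taxa, generated independently of one another;
* detection at day 4 ~ Bernoulli(q_init, default 0.5), later days from a
  first-order Markov chain with stay-probability 0.8 by default —
  colonisation is persistent, a microbe does not simply dissipate — with
  an optional asymmetric pair of stay-probabilities;
* outcome ~ Normal(μ(pattern of one driver taxon), sd 0.94). The sd and
  the default baseline mean (−0.24) are the Normal parameters implied by
  the reference cohort's reported outcome tails (16.7% of infants above
  +0.67, 32.2% below −0.67): solving Φ((0.67−μ)/σ) = 0.833 and
  Φ((−0.67−μ)/σ) = 0.322 gives σ ≈ 0.94, μ ≈ −0.24;
* optional completely-at-random blanking of detection entries
  (`missing_rate`, default 0 — the calibration runs use complete data so
  that the error accounting is exact).

Only the designated driver taxon's pattern moves the outcome mean
(`effect_map`); the other 21 taxa are pure nulls. This is the cleanest
ground truth for mdFDR accounting across the family structure. What the
generator does **not** emulate: dependence among taxa (real probes are
phylogenetically and ecologically correlated), non-Normal outcome tails,
informative missingness, and covariates such as antibiotics or feeding
mode. Passing calibrations therefore show that the procedure controls its
error rate under its own assumptions, not that those assumptions hold in
any particular cohort.

Reproducibility: replicate *i* of a harness run uses the seed
`(master + 9973·i) mod (2^31 − 1)` (`replicate_seed()`), so any replicate
can be regenerated alone; equal seeds give bit-identical cohorts.

## Error accounting in the harness

A false discovery is the rejection of a truly-null component — for the
time-specific analysis also a rejection whose estimated sign contradicts
the truth (the "mixed directional" part). The per-analysis false
discovery proportion is false/total component rejections (0 when none),
and, because strata are separate procedures, a replicate's score is the
mean of its per-stratum proportions; the empirical mdFDR is the mean over
replicates with Monte-Carlo standard error √(p(1−p)/reps). Pooling
rejections across the two independent stratified analyses before forming
the ratio would instead measure the union family-wise rate of two
procedures (≈ 1 − (1 − α)² under a global null), a quantity no single
analysis claims to bound.

The calibration problem sizes — 2,000 replicates for the pattern
pipeline's all-nulls-true simulation and 1,000 for the time-specific
global null, both at the full 218-subject, 22-taxon scale — were chosen
to put the Monte-Carlo standard error near or below 0.7 percentage
points at the nominal 5% level. The recovery study plants a prevalent
early coloniser (driver q_init = 0.8, persistence 0.8) whose day-4
detection marks expected growth (group mean 0) against a faltering
remainder (mean −1.0): the pipeline should report the reduced pattern
`+XXX`, unscreened, and its recovery rate should rise with the cohort
size (checked at n = 50, 108, 400).

## Numerical and degenerate-input choices

* Intensity exactly at a detection threshold dichotomises to
  *non-detected*: "detected" means strictly above the detection limit.
* A pattern with no matching subjects yields an n = 0 group with flagged
  (NA) moments, never an exception; zero-variance groups are inestimable
  or inconclusive rather than infinite statistics.
* `bh_select()` implements the step-up rule directly and is cross-checked
  against both `p.adjust(, "BH")` and a brute-force oracle.
* All findings are a deterministic function of (cohort, configuration);
  nothing in the analysis path consumes random numbers.
* Strata with fewer than two subjects are excluded (with a warning);
  empty stratum labels are reassigned to an explicit `"unlabelled"`
  stratum rather than silently dropped.

## Known limitations

The pattern machinery scales as 2^T and is intended for a handful of time
points; with many time points, neighbouring days should be binned first.
The method cannot adjust for confounding — it is a transparent way to
*select* a reference pattern, after which a regression strategy with
covariates should take over. Multi-taxon joint patterns are out of scope.
Finally, the equivalence findings are only as meaningful as the margin δ:
0.67 is a convention for growth Z-scores, and other outcomes require
their own margin.
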