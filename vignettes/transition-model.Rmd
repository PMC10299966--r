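---
title: "The five-phase mortality transition model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The five-phase mortality transition model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mortrans)
```

## The model

Maternal deaths, stillbirths, and neonatal deaths share causes, risk
factors, and service-delivery platforms, yet are usually tracked with
separate indicators on different denominators. This package works with two
indicators:

* **MMR** — maternal deaths per 100,000 livebirths;
* **SBN** — stillbirths plus neonatal deaths per 1000 total births
  (livebirths + stillbirths), combining the stillbirth rate (SBR, per 1000
  total births) and the neonatal mortality rate (NMR, per 1000 livebirths).

Countries are placed in one of five transition phases by four threshold
pairs ("knots"):

| knot | MMR | SBN |
|------|-----|-----|
| 1    | 700 | 80  |
| 2    | 300 | 55  |
| 3    | 100 | 30  |
| 4    | 20  | 15  |

Phase 1 is the highest-mortality state (MMR ≥ 700 *or* SBN ≥ 80); phase 5
the lowest (MMR < 20 *and* SBN < 15). The defining rule is **dual
passage**: a country reaches the next phase only when *both* indicators
have fallen below the knot, i.e. its phase is the minimum of the two
single-indicator phases. The implied SBN:MMR ratio at the knots
(`knot_ratios()`) rises 11 → 18 → 30 → 75 across the transition: as
mortality falls, stillbirths and neonatal deaths come to dominate maternal
deaths by an ever larger factor.

### Combining SBR and NMR

SBR is per 1000 *total births* while NMR is per 1000 *livebirths*, so
their sum is not exactly a rate on either denominator. `combine_sbn()`
offers both conventions:

* `"approximate"` (default): `sbr + nmr`. The published knots behave as
  such sums (a neonatal threshold of 45 plus a stillbirth contribution of
  35 giving the phase-1 knot of 80), so the simple sum is the default.
* `"exact"`: `sbr + nmr * (1 - sbr/1000)`, which rescales neonatal deaths
  to the total-births denominator. The difference is below 4% even at the
  highest observed stillbirth rates.

Similarly `sbn_to_mmr_ratio()` treats total births as approximately equal
to livebirths (this reproduces the printed knot ratios exactly); when the
livebirth fraction of total births is known it can be supplied as a
correction.

### Boundary convention

Values exactly at a knot stay in the higher-mortality phase, because the
published phase definitions are "≥ 700" for phase 1 and "< 20" for phase 5
on the maternal scale. The same half-open convention is applied at the
intermediate knots; the source text does not state the intermediate rule,
so this is a documented package convention, verified against a brute-force
oracle at every knot boundary in the tests. A consequence worth knowing:
`classify_indicator(300, mmr_knots)` is phase 2, not phase 3.

### Uncertainty sensitivity

Mortality estimates carry wide uncertainty intervals, especially MMR.
`classify_phases()` accepts `variant = "lower"` / `"upper"` to classify
the bounds instead of the point estimates; since lower bounds mean lower
mortality, phases are always ordered lower ≥ point ≥ upper.
`uncertainty_phase_span()` reports the per-country difference between the
two bound classifications and its mean — a one-number summary of how
fragile the phase map is to estimate uncertainty.

## Transition dynamics

`transition_records()` matches countries classified at two time points;
`transition_matrix()` tabulates the 5×5 movement counts (total = number of
matched countries, by construction); `progression_summary()` counts
progression (≥ 1 phase), two-phase advances (reported both as exactly 2
and as ≥ 2), and regression. The eligible denominator defaults to
countries *below phase 5* at the start, because a phase-5 country cannot
progress; an `"all_phases"` denominator is available since published
summaries have used both. Countries observed at only one time point are
excluded and counted, never imputed.

## Phase profiles and benchmarking

`phase_summaries()` pools the countries in each phase and reports the
unweighted country median and quartiles of a covariate (fertility,
coverage, workforce density, ...). Quartiles use the linear-interpolation
convention (`stats::quantile`, type 7) — the common statistical default;
the type is a parameter so other conventions can be compared. Profiles are
computed per reference year rather than pooled across years, so the
stability of phase characteristics over time is itself checkable.
`benchmark_country()` then flags a country's value as typical (inside the
phase IQR) or above/below it, with an optional multiplicative widening of
the band.

Causes of death are collapsed by `cod_group_shares()` into three groups —
infectious causes including abortion complications (group 1), causes tied
to health and nutritional status such as indirect maternal causes,
prematurity, and growth restriction (group 2), and peripartum
complications (group 3) — using editable mapping files shipped under
`inst/extdata/`. Shares are renormalised to 100, so counts and percents
are both acceptable inputs; unmapped causes are an error in strict mode
and routed to "other" (with a message) in lenient mode.

`abortion_score()` scores policy permissiveness as the share of five legal
grounds on which abortion is permitted (life, physical health, mental
health, rape/incest or fetal impairment, on request), 0–100. Equal weights
are the default because no ordinal weighting is published; the weight
vector is a parameter.

## Wealth-quintile equity

For coverage by wealth quintile (q1 poorest … q5 richest),
`quintile_gap()` is the absolute gap q5 − q1 in percentage points, and
`inequality_pattern_index()` implements the inequality patterns index as

> ipi = (q5 − mean) − (mean − q1) = q5 + q1 − 2·mean,

positive when the richest quintile pulls away from the rest (*top*
inequality), negative when the poorest is left behind (*bottom*
inequality). The published description of this index is a single sentence;
the signed form above is a faithful reading of it, and is flagged as a
package interpretation rather than a reproduction of the original
normalisation. Patterns within ±5 percentage points of zero are labelled
*linear*; the tolerance is a parameter. When the national mean is missing
it is replaced by the unweighted quintile mean with a message (true
national means are livebirth-weighted).

## The synthetic generator

`generate_panel()` exists so that every pipeline stage can be validated
against known ground truth without downloading estimate databases or
survey microdata. What it emulates:

* **Phase structure.** Each country gets an intended baseline phase and
  its (MMR, SBN) pair is drawn uniformly inside that phase's threshold
  box, shrunk by a 10% interior margin per side so that classification
  recovers the intended phase exactly (set `margin = 0` to stress-test
  boundary handling). Outer caps of 1200 (MMR) and 130 (SBN) close the
  open-ended phase-1 box at values above any observed national estimate.
* **Correlated indicators.** The combined SBN rate is split into SBR and
  NMR by drawing a stillbirth:neonatal ratio uniformly in 0.7–1.1 (the
  empirically observed band) and solving exactly for the split, so the
  generated ratios always lie in the configured range.
* **Trends.** Between panel years a country either advances one phase
  (per-phase probability, default 0.63 for phases 1–4, matching the
  observed 20-year progression frequency) and is redrawn in the next box,
  or declines along a 2.5%/year annual rate of reduction with lognormal
  noise, clamped to its phase box. Phase regression is not generated by
  default.
* **Uncertainty.** Bounds are symmetric multiples of the point estimate
  (default half-width 0.30, of the order of the published estimate
  intervals). This is a deliberate simplification of the UN estimation
  models' uncertainty propagation, not a claim about them.
* **Covariates.** Drawn around per-phase medians: lognormal for positive
  rates (keeps positivity; the median is exact), truncated normal on
  [0, 100] for coverage percentages. The default medians follow the
  published phase gradients (fertility 6.1/5.4/2.8/2.2/1.5 children per
  woman; first antenatal visit 66→98%; four or more visits 44→94%;
  institutional births 36→99%; caesarean section 2→25%). Fertility IQR
  widths are the published ones; coverage IQR widths are not published and
  were fixed once as monotone gradients narrow enough that the generator's
  own median-recovery guarantee (medians recovered within 10% relative
  error) is sharp at the panel sizes used below.
* **Inequality regimes.** Institutional-birth quintiles are the country's
  coverage plus regime-shaped offsets scaled by a per-phase gap (defaults
  50/45/35/7/3 points): *top* in phases 1–2, *bottom* in phase 3, *linear*
  in phases 4–5. Published analyses describe bottom inequality in phases 3
  *and* 4, but at the phase-4 gap of 7 points a bottom-shaped profile is
  indistinguishable from linear at the 5-point tolerance, so phase 4 is
  generated linear rather than configured with an unrecoverable label.
  Caesarean quintile rows interpolate between per-phase poorest and
  richest medians.
* **Determinism.** One integer seed drives one `set.seed` stream per
  output table (panel, covariates, quintiles), so adding a table never
  perturbs the others and a fixed seed gives bit-identical output.

What it does **not** emulate: real estimation-model uncertainty (shared
covariates between the MMR and SBR estimation models induce correlations
the generator ignores), reporting and misclassification errors in surveys,
phase regression, sub-national heterogeneity, and any real country's
trajectory. Passing the recovery tests therefore shows the *pipeline* is
correct under the assumed data structure, not that the model's phases are
the right description of any real country.

## Numerical choices

* Knot ratios are reported unrounded and rounded (nearest integer, halves
  away from zero), since the published figures are integers printed from
  non-integer arithmetic.
* Undefined ratios (zero denominators) raise an error for scalar input but
  propagate as `NA` with a counted warning in batch input, so one
  degenerate row cannot abort a 150-country run.
* Panel validation collects *all* row-level violations (bound ordering,
  negative rates, out-of-range years, duplicates) and reports them
  together with row numbers, rather than failing at the first.
* Proportions are exact internally and rounded only for display.

## Problem sizes

The validation suite uses grids of 200 × 200 (mmr, sbn) points including
every knot boundary for the classification oracle, 1000 random estimates
for bound-ordering properties, panels of 200 countries per phase for
median/regime recovery (the recovery guarantees are stated for panels of
at least 50 per phase; 200 keeps the sampling error of a phase median
well inside the 10% band), and 1000 randomised draws for conservation
properties. All sizes are package choices balancing statistical
sharpness against a test suite that runs in seconds.

## Limitations

The thresholds are, as in any staging model, partly conventional; the
half-open boundary rule at intermediate knots is a package convention.
The inequality patterns index here is an interpretation of a one-sentence
definition. The abortion-policy score uses equal binary weights over five
grounds. Phase profiles are unweighted country medians — small and large
countries count equally. None of these choices is hidden: each is a
parameter or a documented convention.
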