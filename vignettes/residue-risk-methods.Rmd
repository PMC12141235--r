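---
title: "Measuring pesticide residue risk from vegetable surveillance data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pesticide residue risk from vegetable surveillance data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(vegrisk)
library(dplyr)
```

## The measurement problem

Provincial market-supervision agencies publish batch-level vegetable
inspection results: for each sampled batch, which pesticides were detected
and at what concentration, against legal maximum residue limits (MRLs).
Risk has two sides that a single indicator misses: how *often* a
vegetable violates its limits, and how *badly* it does. A crop that fails
rarely but spectacularly (bean sprouts are the canonical example) is a
different regulatory problem from one that fails often by a small margin.

vegrisk operationalizes a risk index that multiplies the two:

* **P**, the exceedance probability of a stratum — non-compliant batches
  over sampled batches, `P = M / N`;
* **S**, the hazard severity — per batch the *worst-case* dimensionless
  quotient `max_k(C_k / MRL_k)` over its violating residues, averaged
  within the stratum;
* **IR = P × S**, classified against the acceptable level
  `IR₀ = 2% × 1 = 0.02` (the regulatory pass-rate benchmark of 98%,
  times a residue exactly at its limit as the maximal acceptable harm).
  `IR ≥ IR₀` is high risk.

The analytical unit (stratum) is the province × vegetable cell; strata are
pooled to vegetable level or province level by direct weighting: pooled
`P = ΣM / ΣN`, severity as the sampling-weighted mean
`S = Σ(S_ij · N_ij) / ΣN_ij`, and again `IR = P × S`.

## Compliance rules

A batch is non-compliant iff some residue is *strictly* above its MRL, or
a banned pesticide is detected at all. Equality with the limit is
compliant: `S = 1` is defined as the maximum *acceptable* degree of
hazard, so the strict reading is the only one under which the boundary
case is coherent. A compliant batch contributes hazard 0.

Two conventions had to be fixed where no published rule exists:

* **Banned detections without an MRL.** Any detection violates, but no
  denominator exists for the quotient. We use a configurable reference
  limit `Q` (default 0.01 mg/kg, a typical determination-level surrogate)
  and floor the ratio at 1: `max(C/Q, 1)`. The floor guarantees that a
  stratum with violations has severity ≥ 1, which the index's
  interpretation requires. Both `Q` and the floor are `compliance_policy()`
  options. A banned pesticide that *does* carry a table MRL uses the plain
  `C/MRL` quotient (and still violates on any detection); in that corner a
  hazard below 1 is possible and is reported as computed.
* **Pesticides missing from the MRL table.** Treated as a configuration
  gap, not a violation (`no_limit_violates = FALSE` by default), because a
  missing standard row is far more often an incomplete reference table
  than a lawless compound.

## The severity denominator

The one genuinely ambiguous point in the index's definition is the
denominator of the stratum severity. Averaging the worst-case quotient
over *all* `N` batches makes severity a hybrid of frequency and harm (a
stratum of 1,000 batches with one violation at 10× its limit would score
S = 0.01), and is inconsistent with the index's own published behaviour —
strata with any violation carrying severities above 1, and national mean
severities near 4 alongside exceedance probabilities near 2%. Averaging
over the `M` *non-compliant* batches keeps P and S orthogonal: P carries
all the frequency information, S the conditional harm. vegrisk defaults
to the `M` denominator; `s_denominator = "all"` restores the literal
all-batch average, and under that setting the direct-weighted aggregation
is *exactly* the pooled recomputation (a property the test suite asserts).

## Spatial centre of gravity

For each year, provincial risk indices weight the provincial capital
coordinates: `Long_t = Σ Long_i · (IR_it / Σ IR_it)` and likewise for
latitude. The year-over-year displacement is reported three ways:

* `d_degrees` — the Euclidean displacement in degree space;
* `d_km` — the great-circle (haversine) distance at a mean Earth radius
  of 6371 km (configurable). A degree-space length has no unique
  kilometre equivalent (a longitude degree shrinks with latitude), so the
  great-circle distance between the two centroids is the natural
  convention; against the published worked trajectory it reproduces all
  six printed distances within 1%.
* bearing and transfer locus — the four-quadrant arctangent of
  (ΔLong, ΔLa), 0° due north, clockwise. A single-branch arctangent of
  the ratio is quadrant-ambiguous; `atan2` is the standard resolution.
  Labels follow the "origin to destination" phrasing ("Northeast to
  Southwest" for a centroid drifting southwest); pure-cardinal
  displacements keep the cardinal name. A zero displacement has distance
  0 and an undefined (NA) bearing.

Provinces with zero risk in a year carry zero weight; if *all* indices
are zero the centroid is undefined and the function says so rather than
returning an arbitrary point.

## Data cleaning

Raw disclosures are heterogeneous, so ingestion is deliberately strict
and fully audited. Names are harmonized through editable synonym
dictionaries (unmapped names are dropped and counted, never passed
through); concentrations are normalized to mg/kg accepting only the
mg/kg, µg/kg and ppm dialects (unknown units are counted drops); rows
with missing required fields, half-specified measurements or negative
concentrations are counted drops; years outside the configured study
window are counted drops. The cleaning report satisfies
`n_read = n_kept + Σ drops` on every input — the suite asserts this on
randomized messy tables. An optional extreme-outlier rule (drop
measurements above a configurable `C/MRL` cap, default cap 1000) exists
but is **off** by default: with no published definition of "extreme", the
package never silently alters data.

Duplicate `batch_id`s spanning different batches are an error, matching
the sampling protocol's non-duplication guarantee.

## The synthetic generator

Real supervision databases are not redistributable, so `vegrisk` ships a
seeded generator whose defaults emulate the published study conditions:
`survey_scenario()` builds 15 provinces × 12 vegetable categories
over 2021–2023 with heavily skewed batch counts (totalling roughly
30,000–40,000 batches at `scale = 1`, a deliberate scale-down of the
~295,000-record national database that keeps a full pipeline run in
seconds), category exceedance probabilities between ~0.2% and the 0.29
cap (multi-harvest leafy crops highest), and category severity profiles
matching the published national severities (bean sprout rare-but-severe
at a mean multiple of ~17.6). Violating concentrations are drawn as
`MRL × (1 + LogNormal(μ, σ))`, so violations strictly exceed the limit
and stratum severities have the observed heavy upper tail; `σ = 0.8`
by default and `severity_meanlog()` converts a target mean multiple to
μ. One violating residue is planted per non-compliant batch (the
worst-case score consumes only the maximum, so multiple violations would
not change the index), a banned pesticide accounts for ~12% of
violations, and compliant batches receive sub-limit background
detections. A planted geography concentrates risk in northeastern
provinces in 2021 and southwestern ones in 2023, giving the generator a
known ground-truth "Northeast to Southwest" centroid transfer.

What the generator does *not* emulate: the real database's correlation
between provinces and pesticide panels, reporting-format heterogeneity
beyond unit dialects, and any temporal trend finer than the planted
three-year drift. Passing tests therefore demonstrate the pipeline's
arithmetic and invariances on data with the right marginal structure, not
distributional fidelity to any real inspection record.

## Numerical conventions

* All probabilities are fractions internally; percentages, and the
  published three-decimal severity/index precision, appear only at the
  reporting boundary (`format_risk_table()`), using round-half-away-from-
  zero (`round_half_up()`), the convention used in printed regulatory
  tables, rather than IEEE round-half-even.
* Ranking ties break by pooled sample size descending, then key
  alphabetically.
* Strata below 10 sampled batches are flagged `small_sample`, not
  dropped: with 42 of 52 real-world categories below 1% of sampling
  share, deleting thin strata would silently redefine the population.
* `IR = P × S` is maintained as an exact identity at every level (tested
  to machine precision), and the direct-weighted vegetable/province
  probability always equals the pooled-table recomputation exactly.

## Problem sizes used by the test suite

The suite exercises the oracle comparisons at 1,000 random samples
(worst-case scoring vs. a brute-force loop), 1,000 strata (aggregation
vs. pooled recomputation), 200 seeded replicates of a 500-batch stratum
(exceedance-rate recovery within Monte-Carlo error), and a single
2,000-batch stratum at `p = 0.05`, mean severity 5 (parameter recovery
within three standard errors). End-to-end runs use `survey_scenario()`
at reduced `scale` so the whole suite completes in about a minute.

## A worked run

```{r}
run <- run_pipeline(run_config(scenario = survey_scenario(1), seed = 1))
run
glance(run)
head(format_risk_table(run$vegetable_risk), 8)
run$transfers
```

```{r, fig.width = 6, fig.height = 4}
autoplot(run)
autoplot(run, "centroid")
```

## Known limitations

* Vegetable-level severity aggregation weights stratum severities by
  sampled batches `N_ij` even under the non-compliant-denominator
  reading; weighting by `M_ij` would instead reproduce the pooled
  conditional mean. The `N` weighting is kept as the published
  convention; the exact pooled alternative is available by setting
  `s_denominator = "all"`.
* The index has no uncertainty quantification (no intervals on P or S);
  it is a surveillance ranking tool, not an inferential estimator.
* Dietary-exposure risk (intake × residue vs. toxicological reference
  values) is out of scope; the hazard quotient here is defined entirely
  against legal limits.
* The spatial analysis uses provincial capitals as point masses; it
  measures the drift of a risk-weighted administrative distribution,
  not sub-provincial geography.
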