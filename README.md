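# vegrisk

Measurement of pesticide residue risk in vegetables from regulatory
supervision and sampling data.

Market-supervision agencies publish batch-level inspection results —
which pesticides were detected in a sampled vegetable batch, at what
concentration, against which legal maximum residue limit (MRL). vegrisk
turns those records into a two-dimensional risk measurement for analysts
and food-safety regulators: how *often* a vegetable (or a province's
vegetable supply) violates its limits, and how *severe* the violations
are when they happen.

## The index

For a stratum — one province *i* × vegetable category *j* cell — with
*N<sub>ij</sub>* sampled batches of which *M<sub>ij</sub>* are
non-compliant:

- exceedance probability: *P<sub>ij</sub> = M<sub>ij</sub> / N<sub>ij</sub>*
- worst-case hazard of batch *n*:
  *S<sub>ijn</sub> = max<sub>k</sub>( C<sub>ijnk</sub> / MRL<sub>jk</sub> )*
  over its violating residues; the stratum severity *S<sub>ij</sub>* is
  the mean over the non-compliant batches (a config switch restores the
  all-batch denominator)
- risk index: *IR<sub>ij</sub> = P<sub>ij</sub> × S<sub>ij</sub>*

Strata pool to vegetable or province level by direct weighting
(*P = ΣM/ΣN*, *S = Σ S<sub>ij</sub>N<sub>ij</sub> / ΣN<sub>ij</sub>*),
and every index classifies against the acceptable level
*IR₀ = 2% × 1 = 0.02*: at or above is high risk.

A batch is non-compliant iff a residue is **strictly** above its MRL or a
banned pesticide is detected at all. The yearly spatial centre of gravity
of risk is the IR-weighted mean of provincial capital coordinates, with
year-over-year transfer distance (degree-space and great-circle km),
bearing (0° = due north, clockwise) and a quadrant transfer label.

Because real supervision databases are not redistributable, the package
includes a seeded synthetic generator (`survey_scenario()`,
`generate_inspection_data()`) with known ground truth, so the entire
pipeline is testable offline.

## Worked example

```r
library(vegrisk)

run <- run_pipeline(run_config(scenario = survey_scenario(1), seed = 1))
run
#> <vegrisk_run>
#>   batches: 40208 (1748 non-compliant, 4.35%)
#>   strata: 180 | vegetables: 12 | provinces: 15
#>   high-risk vegetables (IR >= 0.02): 10
#>   centroid 2022 -> 2023: Northeast to Southwest, 908.30 km

head(format_risk_table(run$vegetable_risk), 5)
#>    rank vegetable group_count     n     m p_percent     s    ir risk_class
#>   <int> <chr>           <int> <int> <int>     <dbl> <dbl> <dbl> <chr>
#> 1     1 leek               15  3116   351     11.3   9.31 1.05  high
#> 2     2 cowpea             15  3007   344     11.4   7.28 0.833 high
#> 3     3 ginger             15  2497   323     12.9   4.35 0.563 high
#> 4     4 celery             15  3774   226      5.99  8.20 0.491 high
#> 5     5 spinach            15  1215    51      4.2   8.02 0.337 high
```

Reading the table: 11.3% of synthetic leek batches violated a limit
(`p_percent`), the average violating batch peaked at 9.31 times a legal
limit (`s`), and their product `ir = 1.05` is 52 times the acceptable
level — leek ranks first. The planted geography shows up in the
trajectory:

```r
run$transfers
#>   from_year to_year d_degrees  d_km bearing label
#> 1      2021    2022      9.17  936.    223. Northeast to Southwest
#> 2      2022    2023      9.02  908.    238. Northeast to Southwest
```

`tidy(run)` returns the stratum table, `glance(run)` a one-row summary,
`autoplot(run)` / `autoplot(run, "centroid")` the ranking and trajectory
figures. A thin command-line wrapper with `simulate | assess | risk |
centroid | report` subcommands lives at
`system.file("cli", "vegrisk.R", package = "vegrisk")`.

Individual stages are plain functions over data frames:
`read_inspection_records()` → `match_mrl()` → `assess_samples()` →
`stratum_risk()` → `aggregate_risk()` / `descriptive_stats()` /
`composition_stats()` → `risk_centroid()` → `centroid_transfer()`.

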