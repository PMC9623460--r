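# trackfeat

Standardized feature extraction for retrospective observational studies on
OMOP-style clinical event data.

Raw clinical tables (visits, drug exposures, measurements, procedures) are
rarely analysis-ready: the variable a study needs — "minutes of arterial
pressure more than 10% below the patient's baseline during surgery",
"number of potentially inappropriate medications dispensed in the 90 days
before admission" — has to be computed. `trackfeat` implements that
computation as two explicit transformations over two intermediate states:

1. **Track definition** reduces raw events to *tracks*: time-dependent,
   per-statistical-unit states. A track is either a set of half-open valued
   intervals `[start, end) → value` (a stay, a drug exposure, an episode)
   or a piecewise-constant signal (an irregularly sampled vital sign after
   last-observation-carried-forward reconstruction). Operations: concept-set
   selection and mapping, stay/exposure interval construction, milestone
   selection with priority rules, window arithmetic (e.g. the 90 days
   before admission), 1 Hz resampling, relative thresholding, and interval
   algebra (intersection, union, coalescing).
2. **Track aggregation** reduces a track over a *period of interest* to a
   *feature* — a time-independent `(unit, label, value)` triple — with a
   closed catalogue of extraction methods: `min`, `max`, time-weighted
   `mean`/`weighted_average`, `median`, `sum_duration`, `count`,
   `count_distinct`, `exists`, `delay`, `first`, `last`.

Every feature is documented by a 7-item definition (source, statistical
unit, type of track, value rule, final track, period, extraction method)
that serializes losslessly, and tracks/features persist in flat-file
`TRACK` and `FEATURE` tables that follow OMOP naming conventions
(`*_concept_id`, `value_as_number` / `value_as_concept_id`, paired
date/datetime columns), with referential-integrity validation and exact
round-trip.

Time conventions: one study-wide UTC-naive clock at second resolution;
intervals are half-open (`t ∈ [a, b)` iff `a ≤ t < b`); dates promote to
midnight so day-level claims data and second-level monitor data share one
algebra; day-granular stays include the discharge day.

The package ships a seeded synthetic-data generator (`simulate_bundle()`)
that emulates the raw data of eight reference study cases — intraoperative
hypotension, hyperoxemia in the ICU, heart rate around atropine,
ventilation compliance, inappropriate medications, vitamin-K-antagonist
drug interactions, COPD guideline compliance — with planted, exactly-known
truths, plus reference pipelines (`run_case()`) for all eight.

## Worked example

The canonical chain: count the distinct listed (potentially inappropriate)
drugs a patient was exposed to in the 90 days before a hospital stay.

```r
library(trackfeat)

fx <- generate_worked_sc6_fixture()   # 1 stay, 2 listed drugs, 1 decoy
vt <- fx$bundle$tables$visit_occurrence

stays  <- interval_from_fields(vt, concept = "hospital_stay")    # step 1
window <- shift_window(stays, "start", -90 * DAY_S, 0)           # step 2
um     <- tibble::tibble(person_id = vt$person_id,
                         unit_id = vt$visit_occurrence_id)
expo   <- map_track_values(                                      # steps 3-4
  exposure_intervals(fx$bundle$tables$drug_exposure, unit_map = um),
  laroche_list_set())
masked <- intersect_tracks(expo, window)                         # steps 5-6
aggregate_intervals(masked, periods_from_track(window), "count_distinct")
#> <features> 1 value(s), 1 unit(s)
#> # A tibble: 1 × 7
#>   unit_id person_id feature_concept value_num value_concept definition_id
#>   <chr>   <chr>     <chr>               <int> <chr>         <chr>
#> 1 fxv1    fxp1      count_distinct          2 <NA>          <NA>
#> # ℹ 1 more variable: occurrence_id <chr>
```

The value 2 is forced by the fixture: drug A's exposure
`[2021-02-25, 2021-03-07)` and drug B's `[2021-05-20, 2021-06-09)` both
intersect the window `[2021-03-03, 2021-06-01)`; the non-listed drug is
filtered out in the mapping step.

The same computation run as a persisted, provenance-carrying pipeline:

```r
res <- run_case("sc6", fx$bundle, out_dir = "out/sc6")
# out/sc6/TRACK.csv      every intermediate track, one row per interval
# out/sc6/FEATURE.csv    features with definition ids in feature_source_value
# out/sc6/definitions.dcf  the 7-item definitions, re-loadable
```

A command-line layer wraps the same functions:

```sh
exec/trackfeat simulate --scenario sc2 --n 100 --seed 42 --out bundle/
exec/trackfeat run-case --case sc2 --bundle bundle/ --out out/
exec/trackfeat validate --track out/TRACK.csv --feature out/FEATURE.csv
exec/trackfeat describe --definitions out/definitions.dcf
```

## Acceptance script

`scripts/acceptance.R` re-runs the whole stack from scratch: for each of
the eight scenarios it simulates a 50-unit bundle from the given seed,
executes the casebook pipeline, compares every feature against the
simulator's planted answer key, validates the persisted tables, and writes
the results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
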