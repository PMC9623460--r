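---
title: "Tracks and features: a two-step model of clinical feature extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracks and features: a two-step model of clinical feature extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackfeat)
```

## The model

Retrospective observational studies rarely analyze raw clinical records
directly. The variables that enter a regression — exposure durations,
threshold-crossing times, counts of qualifying dispensings — are computed
from heterogeneous, multidimensional, time-stamped events. `trackfeat`
formalizes that computation as two transformations over two intermediate
states:

* **Track definition** — reduce raw events to *tracks*, time-dependent
  states at the dimensionality of the study's statistical unit (a patient,
  a hospital stay, a surgical procedure, a single drug administration).
  This is where all domain expertise concentrates: which codes select the
  events, which of several redundant milestone events marks the start of a
  procedure, how an irregular vital-sign series becomes a step function.
  The space of operations is open-ended.
* **Track aggregation** — reduce one track over a *period of interest* to
  one *feature* value per unit. This step is deliberately simple: a closed
  catalogue of extraction methods (`min`, `max`, time-weighted
  `mean`/`weighted_average`, `median`, `sum_duration`, `count`,
  `count_distinct`, `exists`, `delay`, `first`, `last`).

Splitting the pipeline this way isolates the hard, study-specific work in
the first step and makes the second step mechanical and auditable. Each
feature records 7 items — source, statistical unit, type of track, value
rule, final track, period of interest, extraction method — and these
serialize to a DCF block (`write_definitions()`) that reconstructs the
definition losslessly, so two sites can establish they computed the same
variable.

## Time conventions and their consequences

**Half-open intervals.** Every interval is `[start, end)`: `t` is inside
iff `start ≤ t < end`. This is a choice the underlying formalism leaves
open; we fix it because it makes abutting periods partition time with no
double counting — a stay ending at midnight and a follow-up window
starting at that midnight share no instant — and it gives "an event
exactly at the window end is outside" as a theorem rather than a per-case
decision. `start == end` encodes a zero-duration point event (an
administration, a lab draw).

**One clock, one resolution.** All instants live on a single UTC-naive
clock at whole-second resolution, the finest granularity any of the
reference cases needs (1 Hz signal reconstruction). Calendar dates promote
to midnight, so day-level claims data and second-level monitor data
compose in one algebra. Durations are integer seconds; with integer
endpoints every comparison below the 2^53 double limit is exact, so the
interval algebra has no floating-point edge cases.

**Day-granular stays include the discharge day.** A claims row with
`admission == discharge` is a real one-day stay, so day-level stay
intervals are `[admission, discharge + 1 day)`. Likewise a dispensing with
zero days of supply still evidences exposure on that day and becomes a
1-day exposure. Both conventions are documented here because the source
data genuinely underdetermine them.

## Signals: reconstruction and aggregation

Monitor data arrive irregularly. `resample()` reconstructs a
piecewise-constant signal on a regular grid (default 1 s) by
last-observation-carried-forward — the standard assumption for archived
monitor data, where a value stands until the next archived value — with a
**validity horizon** `max_gap` (default 600 s): a grid point more than
`max_gap` after the last sample is *undefined*, not stale. Undefined time
is first-class: it carries no weight in means, no membership in episodes,
and restricting a signal to a mask (`restrict_signal()`) simply makes it
undefined elsewhere. Linear interpolation is available as an opt-in
alternative (`method = "linear"`) but is not the default, because it
invents values on the closed interval between samples.

Aggregation over a period uses only the defined segments inside it:

* `mean` and `weighted_average` are one operation — the time-weighted mean.
  With 1 s resampling this equals the plain mean of per-second values,
  which is why both names are accepted.
* `median` is defined as the median of the per-second values (the
  value-at-time median on the 1 s grid). Over integer-second segments this
  is computed exactly as a weighted median; no sampling is involved.
* If nothing is defined inside the period the unit yields **no value and
  an exclusion record** — silently imputing 0 would corrupt downstream
  statistics. For the count-like interval methods (`count`,
  `count_distinct`, `sum_duration`, `exists`) an empty period forces the
  value 0, which *is* returned.

`threshold_episodes()` turns a signal into an episode track: maximal
defined spans where the comparison holds, then gaps of at most `merge_gap`
seconds merged, then episodes shorter than `min_duration` dropped. Both
post-processing parameters default to 0 — the formalism is silent on them,
but artifact-rejection practice needs them, so they are exposed rather
than hard-coded. Thresholds may be absolute or a fraction of a per-unit
reference value (`reference_constant()`), encoding "a drop of 20% from the
baseline".

## Interval algebra

`intersect_tracks(a, b)` follows the payload/mask idiom: the covered time
is the set intersection, and the result carries **a's** values. This is
what the canonical medication chain needs — a drug concept must survive
masking by the 90-day window so the final `count_distinct` still sees it.
`union_tracks()` keeps distinct values as distinct records for the same
reason. Both operate per unit on coalesced covered time; `coalesce_tracks()`
(merge overlapping/abutting equal-valued records) is the normal form, and
the test suite checks the algebra against a brute-force per-second
membership oracle, including inclusion–exclusion.

The drug–drug-interaction windows follow the printed rule — observation
starts the day after the two drugs were first administered together and
ends 4 days after the first of the two is discontinued — applied **per
maximal overlap episode**. The rule as stated is ambiguous for patients
re-exposed after a washout; per-episode application is the only reading
that handles re-exposure, and it reduces to the stated rule for a single
episode.

## Milestones and periods of interest

A procedure's start may be documented by several distinct events
(induction, hypnotic administration, intubation, mechanical ventilation).
`select_milestone()` applies a priority list — the highest-priority concept
present wins regardless of which event came first — with a configurable
tie-break (earliest by default) and a fallback (`first`/`last` event of
any kind, or exclusion). Periods of interest are then milestone pairs plus
signed offsets (`build_period()`), or windows derived from a track
(`shift_window()`): the 90 days before admission, the 10 minutes around an
administration. A zero-length period is legal; an inverted one excludes
the unit with a logged reason. Every exclusion anywhere in a pipeline
carries `(unit_id, reason)`, so input units always reconcile with output
units plus exclusions.

## Storage

Tracks and features persist in flat CSV `TRACK` and `FEATURE` tables that
follow OMOP naming rules (`*_concept_id`, `*_type_concept_id`,
`value_as_number`/`value_as_concept_id`, person/visit foreign keys). Two
departures from the narrow reading of that schema are deliberate:

* paired `*_datetime` columns accompany the `*_date` columns (OMOP's
  established convention), because intraoperative tracks are
  second-granular while the date columns remain day-level for
  compatibility — the date column always holds the datetime's date part;
* signals are stored as one row per constant piece, not one row per
  sample, since tracks can be voluminous; undefined gaps appear as
  non-abutting rows and are reconstructed on read.

There is no unit-of-measure column (the schema we extend has none);
measurement units are documented in the definition manifest. Features
carry no time columns at all — time is implicit in the label or the value.
A feature's `feature_source_value` holds the producing definition id, and
`episode_id` discriminates multiple occurrences per person (e.g. per
atropine administration). Writers sort deterministically and assign ids
from 1, so equal collections give byte-identical files; round-trip is the
identity on canonical (coalesced, sorted, defined-support) collections —
a signal's leading/trailing undefined time is not stored, which is the one
intentional loss.

## The synthetic world

`simulate_bundle()` generates OMOP-style raw tables for eight reference
scenarios with planted ground truth. The central design decision: signals
are generated so that **every value change happens exactly at a sample
instant** — the ground-truth step function *is* the LOCF reconstruction of
the emitted samples. Planted truths (below-threshold seconds, window
means, distinct counts) are computed analytically from that step function,
so pipeline recovery is exact, and irregular sampling cannot blur the
answer key. Additive noise beyond the per-sample draws is off by design;
dip values are drawn with a margin on their side of the threshold
(e.g. dips in 78–88% of baseline against a 90% threshold) so no truth ever
rides the boundary.

Stated-world defaults: inter-sample gaps uniform on 15–120 s (typical
monitor archiving), INR measured daily, 90-day medication windows,
10-minute atropine windows, 1–3 planted hypotension dips of 60–600 s per
procedure, hospital stays of 1–14 days, ~20% of persons with two stays
(stays ≥ 200 days apart so the 90-day windows of one person never
interact). One seeded RNG stream drives everything; the caller's RNG state
is restored afterwards; identical seeds give byte-identical bundles.

What a green test does *not* establish: the generator makes no attempt at
clinical plausibility (no pharmacokinetics, no physiologic coupling, no
missingness mechanisms, no coding errors), so recovery of planted truths
validates the *algebra*, not robustness to real-world data quality.

## Choices made where the design was open

* **The hypotension reference value.** "A drop of 10% from the average"
  leaves the averaging window open; using the whole-procedure mean would
  be circular (the dips would drag down their own reference). The casebook
  uses a pre-incision baseline window and flags the ambiguity.
* **The COPD anchor.** "The year following exposure" does not say which
  exposure; the casebook anchors at the first qualifying exposure.
* **Atropine windows near boundaries.** Windows are clipped to the
  signal's defined domain; an administration too close to the start simply
  has less defined time before it (and would be excluded, with a reason,
  only if nothing is defined at all).
* **Administration-level units.** The atropine case's statistical unit is
  a single administration. Tracks stay person-keyed and each
  administration becomes one occurrence period, so features carry the
  person FK plus an `episode_id` — the storage schema's intended
  mechanism — rather than inventing a fake visit per administration.
* **`mark_periods_containing()`** generalizes the "at least n events in
  the window" operation from one window per unit to a track of candidate
  windows; it is the interval-algebra primitive behind "an INR excursion
  occurred inside this interaction window".
* **Definition files as DCF.** The 7-item definitions serialize as
  Debian-control blocks (base R `read.dcf`), one per definition, with
  method parameters as embedded JSON — a standard text format with zero
  added dependencies.

## Known limitations

Terminology hierarchies are out of scope: concept sets are flat lists with
optional dot-stripped prefix matching, not ATC/ICD tree expansions. No SQL
or database deployment — the TRACK/FEATURE tables are flat files. Signal
medians are grid medians by definition; there is no sub-second support.
The CLI is a thin wrapper over the exported functions and adds no
behavior of its own.
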