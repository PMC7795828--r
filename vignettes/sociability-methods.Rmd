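---
title: "Mining sociability patterns and detecting social routine changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining sociability patterns and detecting social routine changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sociability)
```

## The problem

Social activity is a core behavioural marker in mental-health monitoring:
withdrawals from one's usual social rhythm often precede or accompany
depressive episodes. Smartphone sensing pipelines can already infer *social
events* — most commonly conversations, logged as start/end timestamps — so the
question this package addresses is the layer above the sensors: given a stream
of timestamped social events, **when during the day does this person habitually
socialize, and when does that habit change?**

The package provides four connected pieces:

1. an incremental **sociability-pattern miner** that summarizes an event
   stream into per-slot counts and extracts frequent time-of-day intervals;
2. a **change detector** that compares fresh observations and freshly
   extracted patterns against a persisted reference pattern with the Jaccard
   coefficient;
3. an optional **Mamdani fuzzy-inference layer** that replaces the hard
   similarity threshold with a specialist-configurable judgement; and
4. a **synthetic event generator** plus the evaluation protocols used to
   validate the whole chain without access to sensitive real data.

## The mining model

Time of day is discretized into `S = 24 / t` slots of `t` hours
(`slot_grid()`; default `t = 0.5`, i.e. 48 half-hour slots). Each event is
assigned to exactly one slot by its **start** time — durations are carried
through I/O but do not influence the miner, since the routine of interest is
*when social activity begins*. Events crossing midnight keep the slot and
date of their start.

For each context partition the miner keeps only the slot-count array and the
total event count `|n|` — a constant-size summary, so arbitrarily long streams
can be processed incrementally. Extraction then applies three steps:

1. **Candidate threshold.** A slot is a candidate if its count is at least
   `Sth = |n| * theta / S`: `theta` times the count a slot would hold if the
   `|n|` events were spread uniformly over the day. `theta = 1` (the default)
   asks for "more than chance"; `theta = 0` admits every non-empty slot.
   Counts exactly at the threshold are retained (the step function is taken
   as 1 at zero).
2. **Candidate filter.** Non-candidate slots have their counts zeroed; the
   rest keep their counts (`filter_candidate_slots()`, idempotent).
3. **Adjacency grouping.** Maximal runs of adjacent non-zero candidate slots
   are retained if their summed count reaches `phi * |n|` (boundary again
   retained). Retained runs become clock-time intervals
   `[first_slot * t, (last_slot + 1) * t)`.

`phi` (default 0.3) controls how much of the person's total activity an
interval must concentrate before it counts as routine. Both parameters act
monotonically: raising `theta` never adds candidates and raising `phi` never
adds intervals, which makes their effect predictable for a practitioner.

An empty pattern is a legitimate result (a person with no concentrated
routine), and the comparison layer treats two empty patterns as perfectly
similar — absence of routine is itself behaviour, not missing data.

Slots 47 and 0 are *not* adjacent by default: extracted intervals are
presented as day-bounded `[Tstart, Tend)` periods, and a routine that straddles
midnight would otherwise silently merge across a presentation boundary. A
`wrap_midnight` flag in `miner_params()` enables wrap-around runs for night-owl
cohorts where that is the more faithful reading.

## Context partitioning

A *context attribute* (CA) is a label partitioning the stream: the shipped
scales map each calendar date to its weekday (`MONDAY`..`SUNDAY`), to the
broad `WEEKDAY`/`WEEKEND` distinction, or to a single `ALL` label, and
explicit labels (e.g. weather) can ride along on JSON-lines input. An event
carrying several labels updates every matching partition, and mining,
reference patterns, and change decisions are all maintained per CA — a normal
Saturday routine should not be judged against a Monday's.

Slotting and dating are performed on a configured local timezone (default
UTC), since "time of day" only means something on the local clock; the
StudentLife-style CSV dialect carries bare Unix timestamps, so the timezone
is an explicit configuration knob rather than something inferable from data.

## Change detection

Observations are windows of `window_days` (default 7) calendar days,
summarized per CA as the set of slots with at least one event. Patterns are
extracted every `k = observations_per_pattern` windows (default 2; the
counters reset after each extraction so each pattern reflects exactly `k`
observations). Similarity is always the Jaccard coefficient on slot sets,
with `J(empty, empty) = 1` and `J(empty, non-empty) = 0`.

Two decision flows share one rule:

* **Abnormal behaviour** — each observation is compared against the current
  reference pattern; the event fires when the decision rule does.
* **Routine change** — each newly extracted pattern is compared against the
  persisted reference; on firing, the reference is *replaced* by the new
  pattern, so the detector adapts and subsequent observations are judged
  against the new routine. Otherwise the reference is maintained. The first
  extracted pattern becomes the reference silently.

In crisp mode the rule fires when similarity is strictly below the threshold
(equality does not fire — the rule is "below the threshold"). The default
threshold of 0.461 is a cohort-derived operating point: the mean day-to-day
routine stability plus one standard deviation (`change_threshold()` implements
the `mu + sigma` rule, with the *sample* standard deviation, the conventional
cohort estimate).

## The fuzzy layer

A hard threshold is brittle at its boundary: similarity 0.459 and 0.463
receive categorically different labels. The fuzzy mode replaces the rule with
a small Mamdani system (`fis_config()`): two inputs, the specialist's
*sensitivity* and the observed *similarity* (both 0–100), one output *drift*
(0–100), min-AND rule activation, consequent clipping, pointwise-max
aggregation and centre-of-gravity defuzzification on a configurable grid
(default step 0.1; the centroid is scale-invariant and converges as the grid
is refined). Notifications carry the defuzzified value plus the membership
degree of that value in every output term, so downstream consumers see *how
strongly* a change is asserted, not just that it was.

The shipped default configuration uses three overlapping terms per variable.
Sensitivity and drift use the symmetric layout
trapezoid (0,0,20,40) / triangle (25,50,75) / trapezoid (60,80,100,100). For
the **similarity** input we centre the terms on the mid-range —
trapezoid (0,0,30,50) / triangle (30,50,70) / trapezoid (50,70,100,100) —
because that is where routine-change judgements are actually made: cohort
stabilities put the interesting boundary in the 35–55 % band, and terms whose
slopes lie outside that band cannot discriminate a 41 % from a 52 % similarity
at all. Nine rules form a monotone severity table from (low similarity, high
sensitivity) → `change` down to (high similarity, low sensitivity) →
`no_change`. Everything is overridable from a YAML/JSON file
(`read_fis_config()`); full IEC 61131-7 FCL parsing is deliberately out of
scope.

The verdict rule makes the fuzzy output actionable: the event fires when the
output term with the highest membership at the defuzzified value is `change`
(ties break toward the more severe term). Because the verdict comes from a
finite term geometry, the similarity at which it flips is quantized;
`calibrate_sensitivity()` searches the sensitivity axis for the flip point
closest to a desired crisp threshold, which is how the crisp and fuzzy modes
are aligned on the same operating point. With the default configuration the
achievable flip points jump from about 39 % to about 50 % similarity, so a
46.1 % target lands on the 50 % flip — close enough that both modes classify
the same recorded decision flows identically, but worth knowing when
designing custom term shapes.

## The synthetic generator

`persona_profile()` plants per-context clock-time intervals and four
stability controls: `events_per_interval_rate` (Poisson mean per active
interval per day), `p_active` (the probability an interval is expressed on a
given day), `jitter_minutes` (uniform day-level shift of each interval) and
`noise_rate` (Poisson background events uniform over the day). Event
durations are log-uniform between 1 and 30 minutes, realistic for sensed
conversations and irrelevant to the miner. Streams are pure functions of
their seed; cohorts derive per-user seeds from a master seed by a documented
Lehmer-style rule (`derive_seed()`), and `inject_routine_change()` splices two
personas at a chosen day to emulate an abrupt routine change.

The generator emulates what matters to this pipeline — preferred time-of-day
intervals per context, day-to-day reliability, background clutter, abrupt
change — and deliberately not what does not: there is no weekly periodicity
beyond the context scales, no seasonal drift, no sensor-level artefacts
(missed conversations, duplicate detections), and noise is uniform rather
than bursty. Tests passing on this data therefore validate the *algorithmic*
chain; they do not certify performance on any particular sensing stack.

Default study conditions used by the tests and the acceptance script: 24
users over 66 days for cohort protocols; a two-interval persona
(09:00–10:30 and 20:00–21:30) with rate 5 for recovery checks, degraded to
`p_active = 0.8` and `noise_rate = 2` for the noisy variant; an
eight-week persona-switch drill (switch at day 29, disjoint planted
intervals, rate 8) for the change-detection flow; and a cohort stability
gradient running `p_active` 1 → 0.35, jitter 0 → 75 min, noise 0 → 3
events/day. These sizes keep every protocol comfortably inside interactive
runtimes while leaving all effects far from their decision boundaries.

## Evaluation protocols

* **Routine stability** (`routine_stability()`): the mean Jaccard similarity
  between consecutive calendar occurrences of a CA (Monday to next Monday,
  not Monday to Tuesday). Zero-event occurrences contribute empty sets rather
  than being skipped — skipping would bias stability upward for sparse users.
* **Prediction performance** (`prediction_performance()`): the rolling
  protocol — extract a pattern from `k` observations, score it against each of
  the next `k` observations, re-extract from those, repeat; the mean score
  measures how well `k` observations predict upcoming behaviour.
* **Association** (`evaluate_cohort()`): per-user means of both quantities
  and their Pearson correlation per `k`, plus the cohort `mu`, `sigma` and
  the derived `mu + sigma` change threshold.
* **Coverage filter** (`retain_users()`): cohort analyses retain users with
  at least 80 % of study days observed.

On the shipped gradient cohort the correlation between prediction performance
(`k = 2`) and stability is strongly positive, and `k = 1` performs worse than
`k = 2` on average — a single observation is too noisy a basis for a
predictive pattern. Observation windows are consecutive calendar blocks
counted from the stream's first date, not sliding windows; for day-scale CAs
under weekly windows each observation is exactly one day of data, which makes
the two protocols directly comparable.

## Numerical and degenerate-input choices

* Candidate and run boundaries retain equality (unit step taken as 1 at 0).
* `J(empty, empty) = 1`, `J(empty, non-empty) = 0`.
* Crisp decisions fire strictly below the threshold.
* The defuzzifier refuses an identically-zero aggregate (no rule fired —
  "no verdict" rather than an arbitrary number); the change detector treats
  that as a non-firing decision.
* FIS inputs outside their range are clamped with a warning.
* A single-user cohort has `sigma = 0`, so its change threshold equals its
  own stability.
* Generation never perturbs the caller's RNG state (seeds are scoped).

## Known limitations

* Patterns are unions of slots; sub-slot structure is invisible, and the slot
  length trades temporal precision against count robustness.
* Only event start times are modelled; a routine change expressed purely in
  conversation *duration* is invisible to the miner.
* The default FIS term shapes quantize the fuzzy verdict boundary (see
  above); specialists needing a finely-placed boundary should supply custom
  similarity terms.
* The detector holds one reference pattern per context: gradual drifts that
  never cross the threshold in a single step are absorbed without
  notification.
* MQTT publication is not built in; the JSONL sink is canonical and an
  external bridge can forward it.
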