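---
title: "Measuring walking in trips from GPS, accelerometry and a mobility survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring walking in trips from GPS, accelerometry and a mobility survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripwalk)
```

## The measurement problem

Quantifying walking done *inside* trips — especially trips whose main mode
is not walking, such as the access and egress walks around a metro ride —
requires three data streams that no single sensor provides:

* a **GPS track** (one fix every 5 s) giving geometry and timing of
  movement;
* a **waist-worn accelerometer** giving per-epoch vector-magnitude (VM)
  counts and step counts;
* a **prompted-recall mobility survey** in which an interviewer walks the
  participant through their algorithm-processed GPS week, confirming,
  deleting, correcting and recreating visits and trips.

Raw GPS streams systematically overstate distance: a stationary receiver
indoors produces *pseudo-ambulation*, spurious position drift that can
accumulate kilometres per day, and receivers left at home miss whole
trips. Algorithm-only processing removes part of the inflation but
misidentifies travel modes often enough that mode-specific physical
activity estimates built on it are unreliable. The survey step is what
turns the sensor streams into a validated **timetable**: an exact
partition of each surveyed day into *visits*, *trip stages* (unimodal
segments of a trip) and punctual *transfer episodes* between stages.

`tripwalk` implements this chain end to end and, because the cohort data
such a study produces cannot be redistributed, ships a synthetic-world
generator that emulates the study design closely enough to exercise and
validate every processing step.

## The processing chain

1. **Speed filter** (`filter_low_speed`): points below 1 km/h relative to
   the previously retained point are excluded. The speed estimate is
   local: displacement over elapsed time capped at `max_window_s` (15 s).
   Without the cap, a receiver that sits still for hours would need
   kilometres of displacement before any later fix could reach 1 km/h,
   and short trips following long visits would become invisible; the cap
   keeps the filter a greedy single pass (and therefore idempotent) while
   letting genuine movement onsets through immediately.
2. **Visit detection** (`detect_visits`): greedy running-centroid
   clustering. A cluster whose time span reaches `dwell_min_s` (default
   300 s) while staying within `radius_m` (default 50 m) of its running
   centroid is a visit; everything between visits is a move. The
   dwell/radius defaults are conventional stop-detection values — the
   upstream algorithms this emulates do not publish their constants — and
   both are exposed in the configuration.
3. **Stage splitting** (`split_stages`): a move is split where its
   smoothed speed (centred 5-point rolling median) crosses the
   walk/vehicle boundary (7 km/h). Split vertices are snapped to transit
   stations within 75 m, since true mode changes on public transport
   happen at stations; splitting at *every* station passage would shred a
   bus ride along its own line, so station proximity refines split
   placement rather than creating splits.
4. **Mode imputation** (`score_stage`, `impute_modes`): each stage is
   scored per mode as `0.5 * speed-band match + 0.35 * station evidence +
   0.15 * habitual-mode prior`. Station evidence applies to transit modes
   only: 0.6 when both stage endpoints lie within 75 m of stations of the
   mode, 1.0 when a pair of those stations shares a line. Ties break by a
   fixed mode order. The weights and speed bands are design choices
   exposed in `imputation_params()`; the evidence sources (speeds,
   habitual modes, station proximity) are the substantive inputs.
5. **Survey reconciliation** (`reconcile`): algorithm trips are matched to
   recall by interval intersection-over-union (threshold 0.5 — the match
   is human-mediated in the field, so any reasonable overlap rule works
   and this one is symmetric and scale-free). Matched trips keep their
   GPS geometry, clipped to the recalled stage intervals, cleaned within
   a 60 m corridor of the recalled itinerary (`clean_track`; a stage
   losing more than half its vertices is redrawn wholesale), and
   completed to the stage endpoints when the track stops short — the
   survey recreated short missing segments such as station access walks.
   Missed trips are recreated (`source = "recreated"`) from shortest
   street-grid itineraries for street modes and the surveyed itinerary
   for rides; false-positive trips (pseudo-ambulation) dissolve into
   visits.
6. **Classification and exclusions** (`classify_trip`,
   `apply_exclusions`): the crude scheme distinguishes entirely-walked /
   other-active / public-transport / private-motorized /
   long-distance / multi-mode; the detailed scheme splits public
   transport into bus-coach, metro, suburban train and tramway and the
   car into driver and passenger. A trip with two or more distinct
   non-walking groups *at the scheme's granularity* is multi-mode, so the
   detailed multi-mode count always dominates the crude one. Ski/chairlift
   sequences are deleted whole; jogging and dog-walking stages are
   removed individually with their adjacent transfers; long-distance
   train and plane stages are kept — they are transport.
7. **Accelerometer link** (`detect_nonwear`, `steps_per_segment`):
   nonwear is detected from VM counts with the standard 90-min window /
   2-min spike tolerance / 30-min flank rule, implemented on the epoch
   grid directly (an approximation of tools that re-integrate to 1-s
   data). Steps are joined to timetable segments by epoch **midpoint**,
   which is deterministic and conserves daily totals exactly. Trips
   overlapping nonwear at any point are excluded from step analyses at
   the trip level.
8. **Metrics** (`distance_walked_per_trip`, `attribution_shares`,
   `walking_intensity`, `steps_per_8h_wear`, `urbanicity_strata`,
   `kruskal_wallis`): distance walked per trip is the sum of walking-stage
   polyline lengths (transfers are punctual and contribute none); trip
   steps include non-walking stages and transfers; per-day cumulations
   include zeros for participants not using a class; steps are normalised
   per 8 h of wear time so partially worn days stay comparable. Walking
   speed summaries weight by distance walked and cadence summaries by
   duration walked, using inverse-CDF (type-1) quantiles so that the
   weighted and unweighted definitions coincide at unit weights.

## The synthetic world

`generate_world()` builds a 40 x 40 km region around a core city
(radius 5 km), a close-suburb ring (to 12 km) and a far-suburb ring, with
a 500 m street grid and a transit network of bus lines (grid, 3 km apart,
stations every 450 m), metro lines (core only, 1.5 km apart, stations
every 600 m), two tramway lines in the close suburb and four radial
suburban-train lines (stations every 2.5 km). Zone shares are 35/45/20
(core/close/far) and the base trip-mode mixture matches typical observed
shares (42.3% walked, 4.8% other active, 11.8% public transport, 41.1%
car); public-transport and walking supply decline across zones
(factors 1/0.7/0.4 and 1/0.85/0.6) with the freed mass going to the car,
and the metro is only available in the core — so the public-transport
contribution to walking declines monotonically from core to far suburb by
construction.

Public-transport legs are line-aware: the traveller boards the nearest
station of the drawn mode (or drives if none is within 1.5 km), rides to
the station nearest a mode-typical trip length, and alights to a
destination in the station's walkshed. Each trip is walk-access +
transfer + ride + transfer + walk-egress; street-mode trips are single
stages on the grid. Every diary day tiles `[0, 86400)` exactly.

Sensor artefacts (all configurable, all off under `tw_config_clean()`):

* *visit jitter*: AR(1) position noise, stationary sd 3 m. The
  autocorrelated form matters — independent 3 m noise at 5 s sampling
  would inflate the quasi-raw distance by an implausible ~70 km/day,
  whereas autocorrelated drift reproduces inflation of realistic
  magnitude. No noise magnitudes are published for the emulated study;
  these are conventions, not estimates.
* *pseudo-ambulation*: Poisson bursts (0.12 per visit-hour) of 90-fix
  random walks with 30 m steps — the dominant contributor to quasi-raw
  distance inflation.
* *track noise*: AR(1), sd 2 m, on trip fixes.
* *ride artefacts*: underground signal loss (probability 0.7 for metro,
  0.25 for suburban trains) suppressing the ride's fixes, and AR(1)
  along-track progress noise (sd 40 m) emulating stop-and-go running.
  These are what degrade algorithmic public-transport identification
  relative to walking, reproducing the qualitative accuracy ordering.
* *dropout*: with probability 0.05 a whole trip leaves no GPS trace.

The accelerometer draws per-epoch steps from mode-specific cadences
(walking 100 ± 8 steps/min, in-vehicle 0 ± 2, truncated at zero) and VM
counts from Poisson models chosen so wear time is unambiguous; the wear
schedule is 07:00-21:30 (14.5 h, near the wear medians such studies
report). Epoch length defaults to 60 s and is configurable because the
emulated tooling does not document its epoch length.

All randomness derives from one stream per participant seeded by
`(seed, participant)`, so worlds are byte-identical across runs and
invariant to cohort-size changes.

### What the generator does *not* emulate

Transit timetables and headways (rides start when the traveller arrives),
elevation, indoor positioning, within-trip public-transport transfers
between lines, interviewer recall error beyond a Bernoulli recall
probability and Gaussian timestamp noise, and seasonal or weekday
structure. Passing tests on this world therefore show that the chain is
*internally correct* (it recovers what the generator encoded, under the
artefact mechanisms modelled); they cannot show that the defaults match
any particular city's GPS error climate.

## Worked example

```{r example, eval = FALSE}
cfg <- tw_config(seed = 7)
world <- generate_world(cfg, n_participants = 5, n_days = 7)
run <- run_pipeline(world)

# three definitions of daily distance (km): quasi-raw, algorithm, survey
run$three_way$summary

# time-weighted mode agreement, overall and per mode
run$accuracy$mode_agreement
run$accuracy$per_mode

# attribution of distance walked across trip classes
attribution_shares(run$metrics, "distance_walked", "crude")
```

## Numerical and design choices

* **Intervals** are half-open `[start, end)` everywhere, so partitions
  concatenate without gaps; a trip crossing midnight (never generated,
  but handled) belongs to its start day.
* **Distances** are haversine on consecutive lon/lat vertices; no
  projection is used anywhere (matching GPS practice at urban scales).
* **Grid routing** returns the deterministic east-west-then-north-south
  staircase — any monotone staircase is a shortest grid path, and this
  one is the lexicographic tie-break.
* **Timetable timestamps of recreated trips** reuse the recalled
  (diary) boundaries plus optional Gaussian noise. With no GPS at all, a
  real deployment needs another timestamping rule; this is flagged as a
  limitation rather than modelled.
* **Agreement denominators** exclude transfer episodes: their timestamps
  are the least reliable part of the chain (often underground), and the
  report object records `transfers_excluded = TRUE`.
* **Degenerate cases**: the all-ties rank test returns H = 0, p = 1;
  zero-duration walking stages are skipped with a warning in intensity
  summaries; a zero wear-time denominator is an error, not an `Inf`.
* **Problem sizes**: the bundled checks run the full chain on 20
  participants x 7 days (140 participant-days, ~2.4 million GPS fixes),
  which is where the recovery and ordering properties stabilise while
  staying comfortably interactive; unit checks use 2-3 participants over
  2-3 days.

## Known limitations

* The imputation cannot distinguish car driver from passenger, or bus
  from coach — those distinctions exist only after survey validation, and
  the imputed alphabet says so explicitly.
* Walking accuracy on the synthetic world is higher than any field study
  would observe, because walking speeds in the generator sit alone in
  their speed band. The package asserts the *ordering* (walking
  identified better than public transport), never field magnitudes.
* The exclusion bookkeeping is documented per rule; published
  trip-ledger totals from field studies are not decomposable to the rule
  level and are not reproduced as such.
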