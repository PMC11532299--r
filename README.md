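# pirroutines

Behavioral-pattern analysis for in-home PIR motion-sensor streams, aimed at
ambient-assisted-living (AAL) monitoring of older adults living alone.

PIR motion detectors fire on movement, not presence: a still occupant is
invisible, and all a home produces is a time-stamped stream of point events,
one per sensor firing. `pirroutines` turns such streams into interpretable
behavioral measurements:

* **Presence inference** — a silent gap between two firings in the *same*
  room, with no other PIR or entrance-door firing in between, is attributed
  to continued occupancy of that room; cross-room and door-interrupted gaps
  stay *unknown*. Each firing attests presence for at least the sensor hold
  time (default 60 s).
* **Activity profiling** — the daily activity profile of a participant is
  the 24-vector of mean firings per hour of day; population curves report
  the bin-wise mean and first/third quartiles across participants.
* **Behavioral clustering** — profiles are clustered with Euclidean
  K-means (k-means++ seeding, 50 restarts, deterministic under a seed); the
  number of clusters is selected by the mean silhouette
  `s = (b − a) / max(a, b)`, and recovered partitions are scored against
  ground truth with the adjusted Rand index.
* **Circadian events** — wake-up is the first firing outside the bedroom at
  or after 06:00 (bedroom firings never qualify; pre-threshold nycturia
  trips are ignored); bedtime is the last non-bedroom firing before the
  first 60-minute quiet window after 21:00. Weekday and weekend wake times
  are compared with Welch's t-test.
* **Synthetic cohort** — a semi-Markov resident simulator with planted
  wake/bed times, room-sojourn schedules and two behavioral archetypes
  (a gradual midday-peaked routine and a rapid post-wake surge), so every
  stage is testable against known ground truth without any real data.
* **Demographics** — participant-table ingestion, age-based inclusion
  filtering, and a population-sd (divisor N) demographic summary.

## Worked example

Simulate the default 18-home cohort (5 + 13 across the two archetypes,
60 days each) and run the full pipeline:

```r
library(pirroutines)

demographic_summary(example_participants())
#> Cohort: n = 18 (15 F, 3 M)
#> Age: 73.6 +/- 6.3 (F 73.0 +/- 5.3, M 76.7 +/- 9.5)

cfg <- pipeline_config(simulation = simulation_config(seed = 11), seed = 11)
res <- run_pipeline(cfg, "pir_out")
#> pipeline: 18 home(s), 206,300 events

summary(res$clusters)
#> K-means over 18 profiles (seed 11, 50 restarts)
#> K-means activity clustering: k = 2, sizes {13, 5}, WCSS 61.662, mean silhouette 0.815
#>   cluster 1 (peak hour 9): home06, home07, ..., home18
#>   cluster 2 (peak hour 14): home01, home02, home03, home04, home05
```

Silhouette selection lands on two clusters whose mean activity curves peak
at hour 9 (the rapid-morning group) and hour 14 (the gradual-midday group),
and the assignment recovers the planted archetypes exactly
(`res$manifest$clustering$ari_vs_planted` is 1).

```r
res$circadian[["home01"]]
#> Circadian summary home01: 60 days (0 censored)
#>   mean 07:58:26, sd 30.9 min; median 07:53:44 [q05 07:12:30, q95 08:59:14]
#>   weekday 08:00:28 (n=42) vs weekend 07:53:42 (n=18): welch p = 0.388

round(res$occupancy$fraction[res$occupancy$home_id == "home01"], 3)
#> bathroom kitchen bedroom living_room other unknown
#>    0.042   0.132   0.518       0.187 0.098   0.023
```

This home wakes a little before eight with no weekday/weekend difference
(p = 0.39), and spends just over half of each day in the bedroom — the
dominant room, as expected for this population. The report bundle in
`pir_out/` holds every stage's CSVs (profiles, population and per-cluster
curves, occupancy, silhouette table, assignments, wake/bed estimates,
circadian summaries) plus a `manifest.json` recording every tunable; the
same config and seed reproduce the bundle byte for byte.

A thin CLI over the same functions lives at `inst/cli/pir-pipeline.R`
(`simulate`, `analyze` and `demo` subcommands).

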