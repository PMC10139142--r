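# colocnet

Co-location social networks and bedroom privacy in long-term care.

Residents of long-term-care facilities form closed, bounded social
networks: nearly all of their day-to-day contact is with the people who
share their floor. Indoor positioning systems (BLE beacons scanning for
wearable devices) can observe this world sociocentrically — every
tracked resident, every room, second by second. `colocnet` turns such
device–zone location streams into social-network and built-environment
analyses for researchers in environmental gerontology, epidemiology and
network science:

- **Cleaning** of second-level records: exact-duplicate removal,
  majority-vote resolution of cross-talk conflicts, optional flicker
  smoothing, gap bridging that respects sampling blackouts.
- **Meaningful-interaction detection**: two or more tracked residents in
  the same room or space for strictly more than 5 minutes constitute one
  dyadic interaction event; *k* co-present residents yield all *k(k−1)/2*
  dyads.
- **Networks**: the two-mode (resident–location) network and its
  one-mode (resident–resident) projection, with event counts as tie
  strength; GraphML / GEXF / edge-list export.
- **Per-resident features**: partner counts and daily contact
  frequencies stratified by roommate relation × location class, solitude
  episodes, and Freeman-normalised degree centrality
  (partners / (N−1)).
- **Social-cluster typology**: k-means over the nine stratified
  features (k = 1…10, elbow selection, 50 restarts, mandatory seed) with
  rule-based labels — Diverse (common area), Diverse (bedroom),
  Non-roommate-focused, Roommate-focused, Restricted.
- **Bedroom privacy instrument**: five architectural factors (occupancy,
  adjacency, transitional spaces, visibility, visual privacy), each coded
  0–3 or 0–1, summing to a 0–11 total where higher means more privacy.
- **Privacy–network associations**: a 9-outcome × 6-predictor table of
  Pearson correlations (or standardized OLS coefficients) with
  significance tiers, plus honest calibration machinery.
- **Simulator**: an agent-based generator of facility movement and
  sensor noise (85% detection, 2% adjacent-zone duplication, alternating
  recorded hours) with planted social structure and exact ground truth,
  so every stage is testable without confidential data.

## Worked example

Simulate two days of alternating-hour sensing for the default
48-resident facility, run the pipeline, and look at the results:

```r
library(colocnet)

fac <- build_default_facility()
cfg <- simulation_config(facility = fac, n_days = 2, seed = 7)
sim <- simulate_facility(cfg)
nrow(sim$records)
#> [1] 3609145

bundle <- run_pipeline(sim$records, fac, tempfile("demo"),
                       hours_recorded = sampled_hours(cfg),
                       k_range = 1:6, n_restarts = 30, seed = 1)
nrow(bundle$events)          # meaningful interactions detected
#> [1] 4550
bundle$k                     # clusters selected by the elbow rule
#> [1] 3
table(bundle$labels$label)
#>     Diverse (bedroom) Diverse (common area)            Restricted
#>                     1                     1                     1
```

The elbow finds the three planted behaviour blocks, the labelling rules
name them, and the partition recovers the planted structure exactly:

```r
m3 <- bundle$sweep$fits[["k3"]]
adjusted_rand_index(m3$cluster, sim$truth$planted_clusters)
#> [1] 1
```

The privacy instrument scores the four bedroom types:

```r
pa <- assess_facility(fac)
unique(pa[, c("bedroom_type", "total")])
#>        bedroom_type total
#> 1         three_bed     7
#> 4 four_bed_corridor     5
#> 9   four_bed_common     2
#> 13         five_bed     4
```

A total of 7 (three-bed rooms) means the most architectural privacy:
low occupancy, semi-private adjacency, two transitional spaces and beds
shielded from the common areas; a total of 2 (four-bed rooms facing
common areas) means the least. `report_tables(bundle)` renders the
roster-composition, privacy, network-characteristic, typology,
contingency and association tables in their standard report shapes.

A thin command-line wrapper is installed at
`inst/cli/colocnet.R` (`Rscript colocnet.R simulate|privacy|all ...`).

## Method notes

See the methods vignette (`vignettes/colocnet-methods.Rmd`) for the
model and its assumptions, parameter defaults and units, what the
simulator does and does not emulate, numerical choices, and known
limitations.
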