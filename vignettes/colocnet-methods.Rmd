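---
title: "Methods: co-location networks and bedroom privacy in long-term care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-location networks and bedroom privacy in long-term care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colocnet)
```

## The problem

Residents of long-term-care (LTC) facilities live in a bounded social
world: their day-to-day contacts are overwhelmingly the people who share
their floor. Indoor positioning systems (e.g. BLE beacons scanning for
wearable devices) make it possible to observe this world sociocentrically
— every tracked resident, every room, every second — instead of relying
on self-report. `colocnet` implements a full analysis chain for such
data:

1. clean second-level device–zone records;
2. detect *meaningful interaction* events — two or more tracked residents
   in the same room or space for **more than 5 minutes**;
3. build the two-mode (resident–location) network and project it to the
   one-mode (resident–resident) network;
4. compute per-resident network features stratified by roommate relation
   and location class;
5. classify residents into a social-cluster typology with k-means;
6. score the architectural privacy of shared bedrooms with a five-factor
   instrument; and
7. associate privacy with network structure.

Because real tracking data of this kind are confidential, the package
also ships a first-class agent-based simulator whose output exercises
every stage with known ground truth.

## The privacy instrument

Each shared bedroom is scored on five architectural factors; the total
(0–11) increases with privacy:

| factor | coding |
|---|---|
| occupancy | 5+ beds = 0; 4 = 1; 3 = 2; ≤2 = 3 |
| adjacency | public = 0; semi-public = 1; semi-private = 2; private = 3 |
| transitional spaces | none = 0; one = 1; two = 2; ≥3 = 3 |
| visibility | can residents see the common areas? |
| visual privacy | beds visible from common areas = 0; not = 1 |

Two published coding directions exist for the visibility factor: the
instrument text scores *seeing the common areas* as 0, while the applied
per-room scores assign 1 to room types that do see them. Both are
supported (`visibility_coding = "applied"` / `"instrument"`); the default
is the applied direction, which reproduces the published per-room factor
scores (totals 7, 5, 2 and 4 for three-bed, four-bed corridor-facing,
four-bed common-facing and five-bed rooms). We do not guess which
direction was intended; the choice is explicit and documented.

Occupancy is scored from the room's *bed capacity*, an architectural
property, not from how many occupants happened to enrol in a study.

## Cleaning and event detection

Raw streams have three defects the cleaning stage addresses
(`clean_records()`):

* **exact duplicates** are collapsed;
* **conflicting registrations** (one device in two zones in one second,
  from sensor cross-talk) are resolved by majority vote over a ±60 s
  context window; ties go to the zone of the nearest earlier retained
  second, then to the lexicographically smallest zone id;
* **flickers** — an isolated run of at most `flicker_s` seconds in a
  foreign zone flanked on both sides by the same zone — are reassigned to
  the flanking zone. A flicker is what a cross-talk duplicate looks like
  when the true-zone record for that second was itself lost, so no
  per-second conflict exists for the majority vote to see. Smoothing is
  off by default (so conflict-free input passes through unchanged) and
  enabled (`flicker_s = 2`) by the pipeline; without it, a loss rate of
  15% combined with 2% duplication fragments long co-presence episodes
  and roughly doubles event counts.

Cleaned records become half-open presence intervals
(`records_to_intervals()`). Gaps of at most `max_gap_s` (default 60 s)
within the same zone are bridged — this absorbs the ~15% detection loss —
but never across a sampling blackout (an unrecorded clock hour), and a
zone change always breaks the interval. The default of 60 s is a
compromise: long enough that independent per-second losses essentially
never split a genuine dwell (a >60 s all-lost run has probability
$0.15^{60}$), short enough not to paper over genuine absences.

`detect_interactions()` applies the co-presence rule: for each unordered
resident pair and zone, every maximal overlap of presence intervals
strictly longer than `min_duration_s` (default 300 s) is one event; k
co-present residents yield all $\binom{k}{2}$ dyadic events. "More than
5 min" is read strictly (> 300 s), configurable. Interaction direction is
not modelled — the sensor cannot see who initiated contact.

The rule is stated in minutes but the data are second-level; detection
operates on seconds (the default), with `events_to_hourly()` available
for parity with hour-aggregated record keeping.

## Networks and features

The two-mode network links residents to zones they visited (edge weight =
number of distinct visit intervals, or dwell seconds). The one-mode
projection links two residents iff they share at least one event, with
the event count as tie strength; the sum of one-mode edge weights equals
the number of events by construction.

Per-resident features (`compute_features()`) follow the typology's nine
strata: partner counts and daily contact frequencies for (roommates in
own bedrooms, non-roommates in other bedrooms, roommates in common areas,
non-roommates in common areas) plus the solitude frequency (maximal
episodes > 5 min in which the resident shares their zone with no other
tracked resident). Classification of an event: roommate events in a
bedroom are "own bedroom" for both (roommates share one bedroom);
non-roommate events in any bedroom fall in the "other bedrooms" stratum;
all non-bedroom zones count as common space. A partner is counted once
per stratum regardless of event count. Frequencies are events per
observed day with no extrapolation into unsampled hours.

Degree centrality defaults to Freeman-normalised degree on the binarised
network — distinct partners / (N−1), 0 iff isolate. The exact centrality
definition used with legacy network software is not recoverable from
published values, so the package keeps the standard definition and treats
published centrality values as non-reproducible.

## Social-cluster typology

The nine features (z-scored by default so no scale dominates the
Euclidean metric; a raw-scale option is retained) are clustered with
k-means for k = 1…10, best of 50 random restarts, seed mandatory. The
elbow rule picks the interior k maximising the central second difference
of the within-cluster sum of squares, with an explicit manual override,
because cluster solutions must also make conceptual sense. k = n is
handled as the exact degenerate solution (every resident a singleton,
WCSS 0).

Cluster labels are assigned from raw-scale centroids by rules applied in
priority order over still-unlabelled clusters: *Restricted* (smallest
total across all nine features), *Diverse (common area)* (highest
roommate–common-area frequency), *Diverse (bedroom)* (highest bedroom
frequency), *Non-roommate-focused* (highest non-roommate–common-area
frequency), and *Roommate-focused* for the remainder; extra clusters are
"unclassified". Ties break to the lowest cluster index and are flagged.
Typology tables flag cluster means at least 0.5 SD from the overall mean;
the reference SD defaults to the across-resident SD of each feature (the
alternative — SD across cluster means — is selectable, since published
tables do not say which was used).

## Privacy–network associations

The report-shaped association table crosses nine outcomes (degree
centrality + four partner counts + four contact frequencies) with six
predictors (overall privacy + five factors). The default cell statistic
is the zero-order Pearson correlation with its two-sided p-value
(significance tiers `*` p < 0.05, `**` p < 0.01), matching how such
tables are conventionally footnoted; a standardized-OLS mode is also
implemented. Note that the five factor vectors broadcast from four
bedroom types span at most four distinct rows, so the joint OLS is rank
deficient by construction — the package detects this and names the
aliased factors rather than silently dropping them (explicit
`on_collinear = "drop"` is available). Predictors are bedroom-level
scores broadcast to residents; within-bedroom rows are therefore not
independent, which inflates nominal significance — documented as a
caveat, with no mixed model fitted and no multiple-testing correction by
default (a Benjamini–Hochberg flag exists).

`null_calibration()` checks the machinery rather than any substantive
claim: with outcomes drawn as independent noise against a fixed predictor
vector the rejection rate at α = 0.05 should sit in the binomial band
around 0.05, and with a planted standardized effect of d = 1.5
(converted to r = d/√(d²+4) ≈ 0.6) the planted sign should be recovered
essentially always at n = 48. The calibration deliberately re-runs only
the association stage on fresh draws — re-simulating the entire facility
1,000 times would test the same code at three orders of magnitude more
cost.

## The simulator

`simulate_facility()` is the package's stand-in for confidential tracking
data. What it emulates:

* a 48-resident roster across the four shared-bedroom types (7 / 18 / 15 /
  8), with bedroom attributes that reproduce the published privacy scores;
* one month of second-by-second records by default, collected at
  alternating hours across the full 24 h;
* ~85% detection accuracy (independent per-second record loss) and 2%
  duplicate registrations on an adjacent sensor;
* a planted social structure: the roster is partitioned into clusters,
  pairwise visit propensities form strong within-cluster blocks, and each
  cluster follows a distinct day-time behaviour profile.

Movement is a slot-based semi-Markov model (15-minute slots): at night
every resident is in their own bedroom; during the day a resident stays
home, visits another resident's bedroom (host drawn ∝ affinity), or goes
to a common area (favouring the cluster's preferred common zone with
probability 0.6), with class probabilities set by the cluster's profile
(common-oriented 0.30/0.15/0.55, bedroom-oriented 0.20/0.65/0.15,
restricted 0.92/0.02/0.06 over own/other-bedroom/common). The
common-oriented block is deliberately not pushed further: concentrating
one large block in a single zone makes pairwise co-presence grow
quadratically in block size, and a single runaway cluster compresses the
z-scored separation between the remaining blocks.

Two design points deserve emphasis. First, the planted clusters carry
*behavioural profiles*, not just affinity blocks: the typology clusters
residents in feature space, and a pure block-model graph with identical
marginal behaviour would plant community structure that the nine features
cannot see. Second, a co-presence sensor cannot distinguish "restricted"
from "home-body with roommates present" — the restricted profile is
therefore defined by low day-time co-location of every kind, which is the
only notion of restrictedness this instrument can measure.

Ground-truth events are derived directly from the slot occupancy matrix,
never from the record stream, so the detector can be checked against them
as an independent oracle: with lossless sensing the detected event set
equals the ground truth exactly, and under alternating-hour sampling it
equals the ground truth clipped to the recorded hours.

What the simulator does **not** emulate: radio propagation and RSSI
artifacts beyond loss/duplication, staff and visitors (untracked in the
motivating setting), battery/charging downtime, circadian heterogeneity
within the day-time block, or any dependence of behaviour on the privacy
scores themselves. Passing recovery tests on simulated data therefore
shows the chain is correct and well-calibrated under the stated noise
model — not that real facilities satisfy that model. The published
second-level and hourly record totals of the motivating data cannot be
reconciled exactly with 48 devices at alternating hours, so the generator
makes no attempt to match them.

## Numerical and reproducibility choices

* Timestamps are integer epoch seconds; intervals and events are
  half-open `[start, end)`.
* All randomness flows from one integer seed; each resident's trajectory
  uses a deterministically derived substream, so output is byte-identical
  across runs and invariant to evaluation order.
* Report tables round half *away from zero* at 2 decimals (contingency
  percentages at 1); internal computation keeps full precision. Published
  tables are not fully consistent in this respect (one printed share is a
  truncation); half-up is applied uniformly.
* Test and validation problem sizes: recovery analyses simulate 2 days of
  alternating-hour sensing for the 48-resident facility (≈3.6 M records
  per run), chosen because recovery quality saturates there while keeping
  the full suite fast; oracle-equivalence checks use randomized instances
  of ≤5 devices over 2 h, where an exhaustive per-second scan is
  feasible.

## Known limitations

* Co-presence in a zone is a proxy: two residents asleep in a shared
  bedroom count as interacting under the 5-minute rule. Interpreting
  own-bedroom strata requires this caveat.
* Bedroom-level predictors broadcast to residents understate standard
  errors in the association table.
* The typology labelling rules are a faithful encoding of verbal cluster
  characterisations; on data without such structure several clusters can
  tie and are flagged rather than silently renamed.
* The event unit is one maximal dyadic overlap; published frequencies may
  use a different accounting basis, which is why only arithmetic
  derivable from printed inputs is treated as reproducible.
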