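---
title: "Monitoring blood-management documentation with a clinical data warehouse"
author: "bloodcdw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring blood-management documentation with a clinical data warehouse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodcdw)
library(data.table)
```

## The problem

Australian hospitals are accredited against the NSQHS Blood Management
standard, which requires evidence that blood-product transfusions are
properly documented: informed consent, a compatibility check, a recorded
completion, and vital-sign observations (temperature, pulse, blood
pressure, respiratory rate) on a fixed schedule around each transfusion.
All of this evidence lives in the EMR — but as *long-format clinical
events*: one row per consent acknowledgement, per "Initiate transfusion"
task, per single vital-sign reading. There is no transfusion row. Before
any compliance rate can be computed, every individual transfusion must
be *reconstructed* from its scattered events, and that reconstruction
has to survive three awkward properties of real EMR extracts:

1. **Transfusions are split across many records.** Only the Initiate
   event marks that a transfusion began; completion, consent,
   compatibility and every observation must be correlated back to it by
   encounter and time.
2. **Start and end are not linked.** A Complete event names a patient
   and a time, nothing else. It may be missing entirely. With
   simultaneous transfusions the attribution is genuinely ambiguous.
3. **Records become invalid.** Clinical staff correct mistakes
   retrospectively; the EMR keeps the wrong record and adds a new
   physical row with the same logical event key and a higher `UPDT_CNT`
   version. Later extracts can therefore invalidate rows that earlier
   extracts delivered.

`bloodcdw` implements the full pipeline: a versioned event store,
episode reconstruction, interval-based compliance scoring, and a
two-granularity warehouse (an event-level `TRANSFUSION` table and a
`TRANSFUSION_DAILY_FACT` table) feeding dashboard-style status and
history views. A synthetic EMR simulator with ground truth stands in
for the hospital source, so the whole system is testable end to end.

## The observation schedule

An episode starting at $s$ and completing at $e$ is scored on four
intervals, each of which passes only if **all four** vital-sign
categories have at least one reading inside the interval's window set.
All bounds are closed — the policy's phrasing is inclusive ("up to 5
minutes after"), so a reading on the boundary minute counts.

| Interval | Window (defaults, minutes) |
|---|---|
| Baseline | $[s - 60,\; s + 5]$ |
| 15-minute | $[s + 15 \pm 5]$ |
| Hourly $k$ ($k = 1..3$) | $[a + 60k \pm 20]$ for each anchor $a$ |
| Post | $[e,\; e + 60]$ |

The hourly anchors are the transfusion start *and* the 15-minute
observation. Hourly observation $k$ is owed only while the transfusion
is still running: if $e \le s + 60k$, subinterval $k$ is
`NOT_REQUIRED`. Scoring therefore disaggregates the hourly measure into
up to three subintervals, each `REQUIRED_PASS`, `REQUIRED_FAIL` or
`NOT_REQUIRED`; the hourly measure passes iff no subinterval is
`REQUIRED_FAIL`.

```{r windows}
win <- interval_windows(as.POSIXct("2021-12-01 10:00", tz = "UTC"),
                        as.POSIXct("2021-12-01 12:30", tz = "UTC"))
lapply(win[c("BASELINE", "MIN15", "POST")],
       function(w) format(as.POSIXct(w[1, ], tz = "UTC"), "%H:%M"))
required_hourly_subintervals(as.POSIXct("2021-12-01 10:00", tz = "UTC"),
                             as.POSIXct("2021-12-01 12:30", tz = "UTC"))
```

### Design choices in the scoring

Several points of the schedule are under-specified in any written
policy; the package makes each choice explicit, in `window_policy()`:

* **Every 15-minute observation anchors the hourly windows, not only
  the earliest.** With a single earliest anchor, documenting an *extra*
  15-minute reading could move the anchored window and turn a passing
  hourly interval into a failing one. Anchoring at every reading inside
  the 15-minute window keeps scoring monotone — more documentation can
  never score worse — and is the most permissive reading of "in
  relation to either the start of the transfusion or the 15-minute
  observation". We deliberately do **not** chain hour $k$'s window from
  the hour-$(k{-}1)$ observation: the dual anchor is stated only
  relative to the start and the 15-minute reading, and chaining would
  let one late observation drag all later windows with it.
* **Open episodes (no Complete recorded) default to `ASSUME_MAX`**: all
  hourly subintervals up to the maximum are owed. In an audit, a
  missing completion record must not excuse missing observations. The
  alternative `CENSOR` policy (owe subinterval $k$ only when attributed
  documentation demonstrably extends past its window) is retained for
  sensitivity analysis.
* **Post observations are `NOT_ASSESSABLE` without a Complete** —
  scored as neither pass nor fail, with their own denominator — so one
  documentation defect (the missing completion) is not double-counted
  as a second defect (a "missed" post observation whose window nobody
  can place.)
* **Consent lookback defaults to 24 h** before initiation. The standard
  states no validity window for consent; the parameter exists precisely
  so that a hospital can set its own.
* **Any record of a category satisfies the category** — a systolic or a
  diastolic reading both count as blood pressure, any of the four
  temperature source forms counts as temperature.

## Reconstruction and matching

Reconstruction is encounter-local. One episode is created per active
Initiate record, always. A Complete closes the **latest preceding
unmatched** Initiate of its encounter ("closest" and "latest" coincide
once candidates are restricted to Initiates at or before the Complete,
which is the only causally sound reading); exact ties break to the
smallest event key. When more than one candidate existed the episode
carries an `ambiguity_flag` — with simultaneous transfusions the rule
is a heuristic and the flag keeps that visible. A Complete with no
candidate becomes an *orphan*: retained and reported, never silently
dropped, and never an episode of its own.

Observations attach to an episode if they fall in
$[s - 60, \text{horizon}]$, where the horizon is $e + 60$ for closed
episodes and $s + 60 \cdot k_{\max} + 60$ for open ones. Observations
are attributed at encounter level: vitals are measured on the patient,
not the blood product, so one reading may support several concurrent
episodes.

### Versioning and incremental loading

The event store keeps, per logical event key, only the highest version
seen; replaced records go to an append-only superseded log and
out-of-order redeliveries to a stale log, so at all times
$|\text{ingested}| = |\text{active}| + |\text{superseded}| +
|\text{stale}|$. Two rows claiming the same key and version with
different payloads raise a hard error — the version counter is the only
arbiter of recency. The source system distinguishes a *physical row
identifier* (new for every correction) from the *logical event key*
(stable across versions); the store's semantics rest entirely on the
latter.

Because the store converges regardless of delivery order and
reconstruction is encounter-local, ingesting one monthly extract,
thirty daily ones or seven hundred hourly ones yields byte-identical
`TRANSFUSION` and `TRANSFUSION_DAILY_FACT` tables. This
batch/incremental equivalence is the package's central invariant; the
incremental path (`apply_changeset()` rebuilds only encounters named in
the upsert changeset) is an optimization, never a semantic change, and
the test suite holds the two paths equal on simulated streams under
single, daily and hourly batching.

## The two-granularity warehouse

The `TRANSFUSION` table stores one row per reconstructed episode with
its precomputed compliance flags; `TRANSFUSION_DAILY_FACT` aggregates
counts per (date, facility, ward, medical service). The fact table
exists for query speed only — every statistic derived from it must
equal the same statistic recomputed from the event level, and the tests
enforce that for the two reference queries (missing consents in a
month; dimension values ranked by lowest compliance rate) before and
after a correction batch. Rates are compared against a default target
of 80% per measure, overridable per measure. The status view reports a
zero-denominator month as *undefined* rather than as a spurious rate;
the history view emits contiguous series with explicit zero-denominator
gaps, and hour-of-day profiles are recomputed from the event level
because daily facts cannot resolve hours.

## The synthetic cohort simulator

`simulate_cohort()` generates ground-truth episodes and emits them
exactly as an EMR extract would deliver them: one long-format row per
clinical event, never a pre-joined transfusion row. It reproduces the
structural defects the pipeline exists to handle — multi-record
transfusions, missing completions, concurrent episodes sharing a
patient's observations, and (via `inject_corrections()`) superseding
record versions whose corrected row becomes visible 10 minutes to 2
days after the original, so corrections land in later batches.

Its defaults describe a plausible audit month in a mid-size hospital
network: 150 encounters over one calendar month across 3 facilities, 5
wards and 4 medical services; 70/20/10% of encounters receive 1/2/3
episodes; durations uniform on 30–300 minutes (so roughly 89%, 67% and
44% of episodes owe hourly observations 1, 2 and 3); 85% of scheduled
intervals fully documented; consent and compatibility present 90% of
the time; completion recorded 85%; 10% of follow-on episodes concurrent
with their predecessor; 5% of events later corrected. Observation
values are synthetic numbers in plausible clinical ranges — only
presence and timing are scored, so no clinical plausibility beyond that
is modelled. Documentation of the four categories within an interval is
all-or-nothing per interval, which matches how observation panels are
charted in practice and keeps the per-interval probability
interpretable.

Two generator properties matter for testing:

* **Byte determinism.** A fixed seed reproduces the emitted extract
  files byte for byte.
* **Contamination-free placement.** A row emitted for one scheduled
  interval falls inside no other interval's scoring window (hourly rows
  sit in the start-anchored window shrunk by one minute at shared
  boundaries and strictly before the true end; post rows sit past the
  last required hourly window). With no corrections and no concurrency,
  the scored flags therefore reproduce the intended ground truth
  *exactly*, and with per-interval documentation probability $p$ the
  measured pass rates are clean binomial draws — the parameter-recovery
  test holds each measured rate within $3\sqrt{p(1-p)/n}$ of $p$ at
  $n = 2000$.

What the simulator does **not** emulate — and hence what passing tests
do not show about real data: free-text documentation, events recorded
under the wrong encounter, clock skew between wards, result names
outside the configured vocabulary (such rows classify as `OTHER` and
surface as orphans rather than disappearing), and correction rates or
timing patterns of any real hospital (the 5% default is a test-harness
choice, not an empirical claim).

## Numerical and interface choices

* All schedule parameters are integer minutes and all timestamps are
  truncated to minute precision — the schedule itself is specified in
  minutes, and the source charting is minute-grained. Timestamps are
  naive local clock times carried on a fixed axis; timezone conversion
  is out of scope and documented as such.
* Persistence is plain CSV snapshots plus a JSON meta file, one file
  per warehouse table, deterministic byte-for-byte for equal states.
  The store's behavioral contract (trigger-style upsert, invalidation,
  changeset) is independent of the storage engine.
* Ties everywhere break lexicographically on the event key, so every
  stage is deterministic for a given active set.
* Rows failing critical-column or type checks at ingestion are routed
  to a rejects table with a reason (`missing-critical`,
  `bad-timestamp`, `bad-version`), mirroring the defensive filter the
  source extraction applies, and are reported per batch.

## Problem sizes in the test suite

The suite verifies the batching equivalence on 20 simulated streams of
roughly 200 episodes each (about 4,500 event rows, ingested three ways
including ~600 hourly batches), the scoring oracle on 1,000 episodes
under both open-episode policies, and parameter recovery on 2,000
episodes per probability level — sizes at which every property above is
exercised while the whole suite stays comfortably within a routine
check run.

## A worked month

```{r worked, message = FALSE}
d <- tempfile()
cfg <- run_config(list(
  extract_dir = file.path(d, "extracts"),
  warehouse_dir = file.path(d, "warehouse"),
  export_dir = file.path(d, "exports"),
  batching = "daily", seed = 1,
  simulation = list(n_encounters = 60)))
sim <- cmd_simulate(cfg)
cdw <- cmd_ingest(cfg)
cdw
status <- status_view(cdw$daily_fact, "2021-12", targets = cdw$targets)
status[, .(measure, numerator, denominator,
           rate = round(rate, 3), target, met)]
query_missing_consents(cdw$daily_fact, "2021-12")
query_lowest_dimension(cdw$daily_fact, "baseline", "facility", "2021-12")
```

## Limitations

The matcher cannot resolve genuinely simultaneous transfusions beyond
the latest-preceding heuristic plus the ambiguity flag; cross-encounter
matching and inference of missing Initiate records are out of scope, as
is any scoring of observation *values*. The history view's hour
granularity is an hour-of-day profile, not a full hourly time series.
Real-time (push) ingestion is not attempted — the pipeline is batch-pull
at whatever frequency extracts arrive.
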