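# bloodcdw

A clinical data warehouse for monitoring blood-management documentation
compliance from EMR data.

Hospitals accredited against the NSQHS Blood Management standard must
show that every blood-product transfusion was properly documented:
informed consent, a compatibility check, a recorded completion, and
vital-sign observations (temperature, pulse, blood pressure,
respiratory rate) on a fixed schedule around the transfusion. The EMR
holds that evidence only as *long-format clinical events* — one row per
consent acknowledgement, per "Initiate" task, per single vital-sign
reading — and corrections arrive later as superseding record versions.
`bloodcdw` turns batches of such extracts into auditable compliance
metrics:

1. **Extract IO** — reads raw extract CSVs through a configurable
   column map, rejecting (never dropping) rows that fail critical-column
   or type checks.
2. **Event store** — keeps, per logical event key, only the highest
   `UPDT_CNT` version; replaced records go to a superseded log, stale
   redeliveries to a stale log, so `ingested = active + superseded +
   stale` at all times and batches may arrive in any order.
3. **Reconstruction** — one episode per active Initiate; a Complete
   closes the latest preceding unmatched Initiate of its encounter
   (ties break on the event key, multi-candidate matches carry an
   ambiguity flag); consent, compatibility and observations attach by
   time windows; unmatched records become orphans.
4. **Compliance** — scores each episode on seven measures. An interval
   passes when all four vital-sign categories have a reading inside its
   closed window set: baseline `[start − 60, start + 5]` min, 15-minute
   `[start + 15 ± 5]`, hourly `[anchor + 60k ± 20]` for `k = 1..3`
   (anchored at the start and at 15-minute observations; hour `k` is
   owed only if the transfusion runs past it), post
   `[end, end + 60]`. Without a Complete, post is `NOT_ASSESSABLE` and
   open episodes owe all hourly subintervals by default.
5. **Warehouse** — an event-level `TRANSFUSION` table plus a
   `TRANSFUSION_DAILY_FACT` table (counts per date × facility × ward ×
   medical service), with status/history dashboard views against a
   configurable 80% target. Every fact-table statistic equals its
   event-level recomputation, and the final tables are byte-identical
   whether you ingest one monthly extract or hundreds of hourly ones.
6. **Synthetic EMR simulator** — generates ground-truth cohorts and
   emits them as realistic raw extracts (multi-record transfusions,
   missing completions, concurrent episodes, superseding corrections),
   so the whole pipeline is testable without hospital data.

## Worked example

Simulate a 60-encounter audit month, ingest it as daily batches, and
read the December status:

```r
library(bloodcdw)
d <- tempfile()
cfg <- run_config(list(
  extract_dir = file.path(d, "extracts"),
  warehouse_dir = file.path(d, "warehouse"),
  export_dir = file.path(d, "exports"),
  batching = "daily", seed = 1,
  simulation = list(n_encounters = 60)))
cmd_simulate(cfg)
cdw <- cmd_ingest(cfg)
#> ingest extract-2021-12-23.csv: 164 rows (0 rejected), 159 inserts, 3 replacements; episodes 10 open / 52 closed
#> ...
cdw
#> <cdw> 32 batches ingested; 1795 active events; 82 episodes (69 closed); 67 fact rows

status_view(cdw$daily_fact, "2021-12", targets = cdw$targets)
#>          measure numerator denominator  rate target    met
#> 1:       consent        81          82 0.988    0.8   TRUE
#> 2: compatibility        73          82 0.890    0.8   TRUE
#> 3:    completion        69          82 0.841    0.8   TRUE
#> 4:      baseline        68          82 0.829    0.8   TRUE
#> 5:         min15        69          82 0.841    0.8   TRUE
#> 6:        hourly        57          82 0.695    0.8  FALSE
#> 7:          post        56          69 0.812    0.8   TRUE
```

Each row is one measure: `rate = numerator / denominator` against the
80% target. The post denominator is the 69 episodes whose completion
was documented — a missing Complete makes the post window unplaceable,
so it is not double-counted as a failed observation. The hourly measure
fails here because an episode fails it if *any* owed hourly subinterval
lacks a full four-category panel.

The warehouse's reference queries run off the daily fact table and
always agree with the event-level recount:

```r
query_missing_consents(cdw$daily_fact, "2021-12")
#> [1] 1
query_lowest_dimension(cdw$daily_fact, "baseline", "facility", "2021-12")
#>    facility numerator denominator      rate
#> 1:    FAC-1        23          29 0.7931034
#> 2:    FAC-2        21          26 0.8076923
#> 3:    FAC-3        24          27 0.8888889
```

See `vignettes/blood-management-warehouse.Rmd` for the scoring model,
its tunable parameters and the design decisions behind them.

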