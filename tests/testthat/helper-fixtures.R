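# Builders for hand-constructed clinical-event fixtures.

library(data.table)

T0 <- as.POSIXct("2021-12-01 10:00", tz = "UTC")

# T0 + minutes, or parse an absolute "HH:MM" on the fixture day
tmin <- function(m) T0 + m * 60
at <- function(hhmm, day = "2021-12-01") {
  as.POSIXct(paste(day, hhmm), tz = "UTC")
}

.ev_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

# one classified canonical event row
mk_ev <- function(name, time, enc = "ENC-1", key = NULL, val = "x",
                  updt = 1L, pat = NULL, fac = "FAC-1", ward = "WARD-1",
                  svc = "SVC-1", batch = "b1", row = NULL) {
  n <- .ev_counter()
  key <- key %||% sprintf("EV-%04d", n)
  rec <- data.table(
    row_id = row %||% sprintf("R-%04d", n),
    event_key = key,
    patient_id = pat %||% paste0("PAT-", sub("^ENC-", "", enc)),
    encounter_id = enc,
    result_name = name,
    result_value = as.character(val),
    event_dt_tm = time,
    updt_cnt = as.integer(updt),
    facility = fac, ward = ward, medical_service = svc,
    batch_id = batch
  )
  cl <- classify(name)
  rec[, `:=`(role = cl$role, category = cl$category)]
  rec[]
}

mk_events <- function(...) rbindlist(list(...))

# a complete 4-category observation panel at the given minute offsets
mk_obs_panel <- function(offsets, enc = "ENC-1", origin = T0, ...) {
  forms <- c("Heart Rate", "Respiratory Rate", "Temperature Tympanic",
             "Systolic Blood Pressure")
  rbindlist(lapply(offsets, function(off) {
    rbindlist(lapply(forms, function(f) {
      mk_ev(f, origin + off * 60, enc = enc, val = "70", ...)
    }))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run classified records through store + reconstruction + compliance
quick_pipeline <- function(records, policy = window_policy()) {
  st <- ingest_records(event_store(), records)$store
  recon <- build_episodes(st$active, policy)
  comp <- evaluate_compliance(recon, policy)
  list(store = st, recon = recon, compliance = comp,
       transfusion = transfusion_table(recon, comp))
}

# classify a simulated cohort's raw rows
classified_events <- function(truth) {
  ev <- copy(truth$events)
  cl <- classify(ev$result_name)
  ev[, `:=`(role = cl$role, category = cl$category)]
  ev[]
}

# map reconstructed episodes back to ground-truth episode ids
truth_join <- function(recon, truth) {
  init <- truth$events[result_name == "Transfusion Initiated",
                       .(event_key, truth_episode_id)]
  eps <- copy(recon$episodes)
  eps[, truth_episode_id := init$truth_episode_id[match(initiate_key,
                                                        init$event_key)]]
  merge(eps, truth$episodes, by = "truth_episode_id",
        suffixes = c("", ".truth"))
}
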