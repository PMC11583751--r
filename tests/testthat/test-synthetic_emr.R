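# The simulator must emit one long-format row per clinical event, be
# byte-deterministic under a fixed seed, and keep its ground truth
# consistent with what it emitted.

test_that("saturated probabilities document every interval and exactly one Complete", {
  cfg <- simulation_config(
    n_encounters = 1L,
    episodes_per_encounter_prob = c(`1` = 1, `2` = 0, `3` = 0),
    p_obs_interval = c(BASELINE = 1, MIN15 = 1, HOURLY = 1, POST = 1),
    p_completion_recorded = 1, p_consent = 1, p_compatibility = 1,
    p_concurrent = 0, p_correction = 0, seed = 3)
  truth <- simulate_cohort(cfg)
  expect_equal(nrow(truth$episodes), 1L)
  ev <- classified_events(truth)
  expect_equal(sum(ev$role == "COMPLETE"), 1L)
  expect_equal(sum(ev$role == "INITIATE"), 1L)

  ep <- truth$episodes
  obs <- ev[role == "OBSERVATION"]
  win <- interval_windows(ep$start_time, ep$end_time,
                          obs_times = obs$event_dt_tm)
  intervals <- c("BASELINE", "MIN15",
                 paste0("HOURLY_", which(ep$duration_min > 60 * 1:3)),
                 "POST")
  for (iv in intervals) {
    cats <- categories_present(
      data.frame(category = obs$category, obs_time = obs$event_dt_tm),
      win[[iv]])
    expect_length(cats, 4L)
  }
})

test_that("probability-zero event types are never emitted", {
  cfg <- simulation_config(n_encounters = 25L, p_consent = 0, seed = 5)
  truth <- simulate_cohort(cfg)
  expect_false(any(truth$events$result_name == "Blood Product Consent"))
  expect_false(any(truth$episodes$consent_given))
})

test_that("a fixed seed reproduces the cohort and the extract bytes", {
  cfg <- simulation_config(n_encounters = 10L, seed = 7)
  t1 <- simulate_cohort(cfg)
  t2 <- simulate_cohort(cfg)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$episodes, t2$episodes)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- emit_extracts(inject_corrections(t1), "daily", d1)
  p2 <- emit_extracts(inject_corrections(t2), "daily", d2)
  expect_identical(basename(p1), basename(p2))
  for (i in seq_along(p1)) {
    expect_identical(readBin(p1[i], "raw", file.size(p1[i])),
                     readBin(p2[i], "raw", file.size(p2[i])))
  }
})

test_that("invalid configuration errors name the offending field", {
  expect_error(simulation_config(p_consent = 1.5), "p_consent")
  expect_error(simulation_config(p_concurrent = -0.1), "p_concurrent")
  expect_error(simulation_config(n_encounters = 0), "n_encounters")
  expect_error(
    simulation_config(time_span = c("2021-12-31 00:00", "2021-12-01 00:00")),
    "time_span")
  expect_error(simulation_config(duration_minutes_range = c(10, 400)),
               "duration_minutes_range")
  expect_error(
    simulation_config(episodes_per_encounter_prob = c(`1` = 0.5, `2` = 0.2, `3` = 0.2)),
    "episodes_per_encounter_prob")
})

test_that("correction injection supersedes, never overwrites", {
  cfg <- simulation_config(n_encounters = 8L, p_correction = 0, seed = 11)
  truth <- simulate_cohort(cfg)

  # p = 0 is a no-op
  expect_identical(inject_corrections(truth, p_correction = 0), truth)

  # p = 1 adds exactly one superseding row per original
  n <- nrow(truth$events)
  corrected <- inject_corrections(truth, p_correction = 1, seed = 99)
  expect_equal(nrow(corrected$events), 2L * n)
  versions <- corrected$events[, .(v = sort(updt_cnt)), by = event_key]
  expect_true(all(versions[, .(ok = identical(v, c(1L, 2L))), by = event_key]$ok))
  # fresh physical row ids, same logical keys
  expect_equal(anyDuplicated(corrected$events$row_id), 0L)

  # an Initiate correction moves the ground-truth start earlier
  init_keys <- truth$events[result_name == "Transfusion Initiated", event_key]
  v2 <- corrected$events[event_key %in% init_keys & updt_cnt == 2L]
  v1 <- truth$events[event_key %in% init_keys & updt_cnt == 1L]
  setkey(v2, event_key); setkey(v1, event_key)
  expect_true(all(v2$event_dt_tm < v1$event_dt_tm))
  tid <- v2$truth_episode_id[1L]
  expect_equal(corrected$episodes[truth_episode_id == tid, start_time],
               v2[truth_episode_id == tid, event_dt_tm])
  # corrections surface later than the event they supersede
  expect_true(all(v2$extract_dt_tm > v1$event_dt_tm))
})

test_that("batching partitions the row set by visibility time", {
  cfg <- simulation_config(n_encounters = 12L, seed = 13)
  truth <- inject_corrections(simulate_cohort(cfg))

  d <- withr::local_tempdir()
  single <- emit_extracts(truth, "single", file.path(d, "s"))
  expect_length(single, 1L)
  hourly <- emit_extracts(truth, "hourly", file.path(d, "h"))

  read_all <- function(paths) {
    rec <- rbindlist(lapply(paths, function(p) read_extract(p)$records))
    rec[, batch_id := NULL]
    setorderv(rec, c("row_id"))
    rec[]
  }
  expect_identical(read_all(hourly), read_all(single))

  # a long transfusion's Initiate and Complete land in different hourly files
  cfg2 <- simulation_config(
    n_encounters = 1L, episodes_per_encounter_prob = c(`1` = 1, `2` = 0, `3` = 0),
    duration_minutes_range = c(180L, 200L), p_completion_recorded = 1,
    p_correction = 0, seed = 2)
  t2 <- simulate_cohort(cfg2)
  d2 <- withr::local_tempdir()
  paths2 <- emit_extracts(t2, "hourly", d2)
  find_batch <- function(name) {
    hits <- vapply(paths2, function(p) {
      any(read_extract(p)$records$result_name == name)
    }, logical(1L))
    basename(paths2[hits])
  }
  expect_false(identical(find_batch("Transfusion Initiated"),
                         find_batch("Transfusion Completed")))

  expect_error(emit_extracts(t2, "weekly", d2))
})

test_that("emitted rows reproduce the ground-truth documentation flags", {
  cfg <- simulation_config(
    n_encounters = 150L,
    episodes_per_encounter_prob = c(`1` = 1, `2` = 0, `3` = 0),
    p_obs_interval = c(BASELINE = 0.7, MIN15 = 0.7, HOURLY = 0.7, POST = 0.7),
    p_concurrent = 0, p_correction = 0, seed = 17)
  truth <- simulate_cohort(cfg)
  pl <- quick_pipeline(classified_events(truth))
  m <- merge(truth_join(pl$recon, truth), pl$compliance, by = "episode_id")

  expect_equal(nrow(m), nrow(truth$episodes))
  expect_identical(m$baseline_pass, m$doc_baseline)
  expect_identical(m$min15_pass, m$doc_min15)
  expect_identical(m$consent_documented, m$consent_given)
  expect_identical(m$compatibility_documented, m$compatibility_given)
  expect_identical(m$completion_documented, m$completion_recorded)

  closed <- m[status == "CLOSED"]
  expect_identical(closed$post_pass == "PASS", closed$doc_post)
  hd <- strsplit(closed$hourly_detail, ";")
  for (i in seq_len(nrow(closed))) {
    for (k in 1:3) {
      intended <- closed[[paste0("doc_hourly_", k)]][i]
      got <- hd[[i]][k]
      if (is.na(intended)) {
        expect_identical(got, "NOT_REQUIRED")
      } else {
        expect_identical(got,
                         if (intended) "REQUIRED_PASS" else "REQUIRED_FAIL")
      }
    }
  }
})
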