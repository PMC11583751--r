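# Episode reconstruction: one episode per Initiate, latest-preceding
# Complete matching, encounter-local observation attribution.

test_that("an Initiate with a later Complete closes into one episode", {
  recs <- mk_events(
    mk_ev("Transfusion Initiated", T0, val = "RBC", key = "I1"),
    mk_ev("Transfusion Completed", tmin(120), val = "RBC", key = "C1")
  )
  recon <- build_episodes(recs)
  expect_equal(nrow(recon$episodes), 1L)
  expect_equal(nrow(recon$orphans), 0L)
  ep <- recon$episodes
  expect_identical(ep$status, "CLOSED")
  expect_identical(ep$episode_id, "EP-I1")
  expect_identical(ep$complete_key, "C1")
  expect_identical(ep$end_time, tmin(120))
  expect_identical(ep$product_type, "RBC")
  expect_false(ep$ambiguity_flag)
})

test_that("a Complete with no matchable Initiate is an orphan, never an episode", {
  recs <- mk_events(mk_ev("Transfusion Completed", tmin(60), key = "C1"))
  recon <- build_episodes(recs)
  expect_equal(nrow(recon$episodes), 0L)
  expect_equal(nrow(recon$orphans), 1L)
  expect_identical(recon$orphans$orphan_reason, "no-initiate-in-encounter")

  # an Initiate strictly after the Complete is no candidate either
  recs2 <- mk_events(
    mk_ev("Transfusion Initiated", tmin(60), key = "I1"),
    mk_ev("Transfusion Completed", tmin(30), key = "C1")
  )
  recon2 <- build_episodes(recs2)
  expect_equal(nrow(recon2$episodes), 1L)
  expect_identical(recon2$episodes$status, "OPEN")
  expect_identical(recon2$orphans$orphan_reason, "unmatched-complete")
})

test_that("a Complete closes the latest preceding Initiate and flags ambiguity", {
  recs <- mk_events(
    mk_ev("Transfusion Initiated", at("10:00"), key = "I1"),
    mk_ev("Transfusion Initiated", at("11:00"), key = "I2"),
    mk_ev("Transfusion Completed", at("12:00"), key = "C1")
  )
  recon <- build_episodes(recs)
  eps <- recon$episodes
  expect_equal(nrow(eps), 2L)
  expect_identical(eps[initiate_key == "I2", complete_key], "C1")
  expect_identical(eps[initiate_key == "I2", status], "CLOSED")
  expect_true(eps[initiate_key == "I2", ambiguity_flag])
  expect_identical(eps[initiate_key == "I1", status], "OPEN")
  expect_true(is.na(eps[initiate_key == "I1", complete_key]))
  expect_equal(nrow(recon$orphans), 0L)
})

test_that("match_complete picks latest time, breaks ties on event key", {
  cand <- mk_events(
    mk_ev("Transfusion Initiated", at("09:00"), key = "I1"),
    mk_ev("Transfusion Initiated", at("10:30"), key = "I2")
  )
  cmp <- mk_ev("Transfusion Completed", at("11:00"), key = "C1")
  pick <- match_complete(cand, cmp)
  expect_equal(as.integer(pick), 2L)
  expect_equal(attr(pick, "n_candidates"), 2L)

  late <- mk_events(mk_ev("Transfusion Initiated", at("12:00"), key = "I3"))
  none <- match_complete(late, cmp)
  expect_equal(as.integer(none), 0L)
  expect_equal(attr(none, "n_candidates"), 0L)

  tie <- mk_events(
    mk_ev("Transfusion Initiated", at("10:00"), key = "I-B"),
    mk_ev("Transfusion Initiated", at("10:00"), key = "I-A")
  )
  expect_equal(as.integer(match_complete(tie, cmp)), 2L)  # I-A < I-B
})

test_that("observation attribution windows are closed and role-aware", {
  recs <- mk_events(
    mk_ev("Transfusion Initiated", T0, key = "I1"),
    mk_ev("Transfusion Completed", tmin(120), key = "C1"),
    mk_ev("Heart Rate", tmin(-30), key = "O1", val = "70"),
    mk_ev("Heart Rate", tmin(-120), key = "O2", val = "71"),
    mk_ev("Blood Product Consent", tmin(-120), key = "CS1")
  )
  recon <- build_episodes(recs)
  # obs at start - 30 attaches; obs at start - 2 h is outside [start - 60, horizon]
  expect_identical(recon$observations$event_key, "O1")
  expect_identical(recon$orphans[orphan_reason == "unattached-observation",
                                 event_key], "O2")
  # but a consent 2 h before start is inside the consent lookback
  expect_identical(recon$episodes$consent_key, "CS1")

  # boundary: exactly at start - 60 attaches (closed bound)
  recs2 <- rbind(recs, mk_ev("Heart Rate", tmin(-60), key = "O3", val = "72"))
  expect_true("O3" %in% build_episodes(recs2)$observations$event_key)
})

test_that("concurrent episodes share encounter-level observations", {
  recs <- mk_events(
    mk_ev("Transfusion Initiated", at("10:00"), key = "I1"),
    mk_ev("Transfusion Initiated", at("11:00"), key = "I2"),
    mk_ev("Transfusion Completed", at("12:00"), key = "C1"),
    mk_ev("Transfusion Completed", at("13:30"), key = "C2"),
    mk_ev("Heart Rate", at("10:30"), key = "O1", val = "70")
  )
  recon <- build_episodes(recs)
  # the 10:30 reading is inside both episodes' attribution windows
  expect_identical(sort(recon$observations$episode_id),
                   c("EP-I1", "EP-I2"))
  expect_identical(unique(recon$observations$event_key), "O1")
})

test_that("attach_observations matches the batch reconstruction", {
  recs <- mk_events(
    mk_ev("Transfusion Initiated", T0, key = "I1"),
    mk_ev("Transfusion Completed", tmin(90), key = "C1"),
    mk_ev("Blood Compatibility Check", tmin(-15), key = "CP1"),
    mk_ev("Heart Rate", tmin(15), key = "O1", val = "70")
  )
  recon <- build_episodes(recs)
  out <- attach_observations(recon$episodes[1L], recs)
  expect_identical(out$episode$compatibility_key, "CP1")
  expect_identical(out$observations$event_key,
                   recon$observations$event_key)
})

test_that("incremental changeset application equals a full rebuild", {
  # late-arriving Complete closes a previously open episode
  b1 <- mk_events(mk_ev("Transfusion Initiated", T0, key = "I1"))
  b2 <- mk_events(mk_ev("Transfusion Completed", tmin(100), key = "C1"))

  up1 <- ingest_records(event_store(), b1)
  r1 <- apply_changeset(build_episodes(data.table()), up1$changeset, up1$store)
  expect_identical(r1$episodes$status, "OPEN")

  up2 <- ingest_records(up1$store, b2)
  r2 <- apply_changeset(r1, up2$changeset, up2$store)
  expect_identical(r2$episodes$status, "CLOSED")
  expect_identical(r2, build_episodes(up2$store$active))

  # a corrected Initiate timestamp moves the start and re-attributes
  b3 <- mk_events(mk_ev("Heart Rate", tmin(-70), key = "O1", val = "70"))
  up3 <- ingest_records(up2$store, b3)
  r3 <- apply_changeset(r2, up3$changeset, up3$store)
  expect_equal(nrow(r3$observations), 0L)  # -70 is outside [start - 60, ...]

  corr <- mk_ev("Transfusion Initiated", tmin(-15), key = "I1", updt = 2L)
  up4 <- ingest_records(up3$store, corr)
  r4 <- apply_changeset(r3, up4$changeset, up4$store)
  expect_identical(r4$episodes$start_time, tmin(-15))
  expect_identical(r4$observations$event_key, "O1")  # now inside the window
  expect_identical(r4, build_episodes(up4$store$active))

  # empty changeset leaves the result untouched
  expect_identical(apply_changeset(r4, bloodcdw:::empty_changeset(),
                                   up4$store), r4)
})

test_that("incremental folding equals one-shot reconstruction on random streams", {
  for (seed in c(101, 102, 103)) {
    cfg <- simulation_config(n_encounters = 15L, seed = seed)
    truth <- inject_corrections(simulate_cohort(cfg), p_correction = 0.15,
                                seed = seed + 1L)
    ev <- classified_events(truth)
    setorderv(ev, c("extract_dt_tm", "row_id"))
    splits <- withr::with_seed(seed, sort(sample(nrow(ev), 4L)))
    groups <- findInterval(seq_len(nrow(ev)), splits + 1L)
    st <- event_store()
    recon <- build_episodes(data.table())
    for (g in sort(unique(groups))) {
      up <- ingest_records(st, ev[groups == g])
      st <- up$store
      recon <- apply_changeset(recon, up$changeset, st)
    }
    expect_identical(recon, build_episodes(st$active))
    # one episode per active Initiate, always
    expect_equal(nrow(recon$episodes), sum(st$active$role == "INITIATE"))
    # attribution never crosses encounters
    m <- merge(recon$observations, recon$episodes[, .(episode_id, encounter_id)],
               by = "episode_id", suffixes = c("", ".ep"))
    expect_identical(m$encounter_id, m$encounter_id.ep)
  }
})
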