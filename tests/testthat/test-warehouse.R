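# Daily aggregation, the two reference queries, and the dashboard views.

# a small deterministic cohort shared by the warehouse tests
wh_fixture <- function(seed = 31, n = 40L) {
  cfg <- simulation_config(n_encounters = n, seed = seed)
  truth <- simulate_cohort(cfg)
  pl <- quick_pipeline(classified_events(truth))
  list(truth = truth, pl = pl, facts = aggregate_daily(pl$transfusion))
}

test_that("daily aggregation counts what it groups", {
  tf <- data.table(
    episode_id = sprintf("EP-%d", 1:5),
    start_time = c(rep(at("10:00"), 3L), at("09:00", "2021-12-02"),
                   at("09:00", "2021-12-02")),
    facility = "FAC-1",
    ward = c(rep("WARD-1", 3L), "WARD-1", "WARD-2"),
    medical_service = "SVC-1",
    status = "CLOSED",
    consent_documented = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    compatibility_documented = TRUE,
    completion_documented = TRUE,
    baseline_pass = TRUE, min15_pass = TRUE, hourly_pass = TRUE,
    post_pass = c("PASS", "FAIL", "PASS", "PASS", "NOT_ASSESSABLE")
  )
  facts <- aggregate_daily(tf)
  expect_equal(nrow(facts), 3L)  # (day1 w1), (day2 w1), (day2 w2)
  d1 <- facts[date == as.Date("2021-12-01")]
  expect_equal(d1$n_transfusions, 3L)
  expect_equal(d1$n_consent_pass, 2L)
  expect_equal(d1$n_post_pass, 2L)
  expect_equal(d1$n_post_assessable, 3L)
  expect_equal(sum(facts$n_transfusions), nrow(tf))
  expect_equal(nrow(aggregate_daily(tf[0L])), 0L)
})

test_that("fact-table invariants hold on simulated data", {
  f <- wh_fixture()$facts
  counts <- c("n_consent_pass", "n_compatibility_pass",
              "n_completion_documented", "n_baseline_pass", "n_min15_pass",
              "n_hourly_pass", "n_post_assessable")
  for (cl in counts) {
    expect_true(all(f[[cl]] >= 0L & f[[cl]] <= f$n_transfusions))
  }
  expect_true(all(f$n_post_pass <= f$n_post_assessable))
})

test_that("missing-consent query matches the event-level recount", {
  one <- data.table(date = as.Date("2021-12-05"), facility = "F", ward = "W",
                    medical_service = "S", n_transfusions = 5L,
                    n_consent_pass = 3L)
  for (cl in setdiff(names(bloodcdw:::empty_daily_fact()), names(one))) {
    one[, (cl) := 0L]
  }
  expect_equal(query_missing_consents(one, "2021-12"), 2L)
  expect_warning(expect_equal(query_missing_consents(one, "2022-03"), 0L),
                 "no fact rows")

  fx <- wh_fixture()
  got <- query_missing_consents(fx$facts, "2021-12")
  event_level <- fx$pl$transfusion[format(start_time, "%Y-%m") == "2021-12" &
                                     !consent_documented]
  expect_equal(got, nrow(event_level))
})

test_that("lowest-dimension ranking is ascending and matches event level", {
  fx <- wh_fixture()
  rk <- query_lowest_dimension(fx$facts, "baseline", "facility",
                               period = "2021-12")
  expect_false(is.unsorted(rk$rate))
  # recompute one facility's rate from the event-granularity table
  tf <- fx$pl$transfusion[format(start_time, "%Y-%m") == "2021-12"]
  for (i in seq_len(nrow(rk))) {
    sub <- tf[facility == rk$facility[i]]
    expect_equal(rk$rate[i], mean(sub$baseline_pass))
  }
  single <- query_lowest_dimension(fx$facts[facility == "FAC-1"],
                                   "consent", "facility")
  expect_equal(nrow(single), 1L)
  expect_error(query_lowest_dimension(fx$facts, "nonsense", "facility"),
               "unknown measure")
  expect_error(query_lowest_dimension(fx$facts, "consent", "postcode"),
               "unknown dimension")
})

test_that("status view compares rates to targets and flags empty months", {
  fx <- wh_fixture()
  sv <- status_view(fx$facts, "2021-12")
  expect_identical(sv$measure, cdw_measures())
  tf <- fx$pl$transfusion
  expect_equal(sv[measure == "consent", rate], mean(tf$consent_documented))
  expect_equal(sv[measure == "post", denominator],
               sum(tf$post_pass != "NOT_ASSESSABLE"))
  expect_identical(sv$met, sv$rate >= sv$target)

  empty <- status_view(fx$facts, "2022-06")
  expect_true(all(empty$undefined))
  expect_true(all(is.na(empty$rate)))

  # a saturated cohort meets an 0.8 target on every measure
  sat <- simulation_config(
    n_encounters = 15L,
    p_obs_interval = c(BASELINE = 1, MIN15 = 1, HOURLY = 1, POST = 1),
    p_consent = 1, p_compatibility = 1, p_completion_recorded = 1,
    p_correction = 0, seed = 37)
  spl <- quick_pipeline(classified_events(simulate_cohort(sat)))
  ssv <- status_view(aggregate_daily(spl$transfusion), "2021-12")
  expect_true(all(ssv$met))
})

test_that("history series conserve totals across granularities", {
  fx <- wh_fixture(seed = 41, n = 60L)
  months <- history_view(fx$facts, "month")
  days <- history_view(fx$facts, "day")
  expect_equal(length(unique(months$period)),
               length(unique(format(fx$facts$date, "%Y-%m"))))
  # day-level numerators sum to month totals, measure by measure
  for (m in cdw_measures()) {
    expect_equal(sum(days[measure == m, numerator]),
                 sum(months[measure == m, numerator]))
  }
  # the day series is contiguous: gaps appear with zero denominators
  span <- seq(min(fx$facts$date), max(fx$facts$date), by = "day")
  expect_identical(unique(days$period), format(span, "%Y-%m-%d"))
  missing_days <- setdiff(format(span, "%Y-%m-%d"),
                          format(fx$facts$date, "%Y-%m-%d"))
  if (length(missing_days)) {
    expect_true(all(days[period %in% missing_days, denominator] == 0L))
    expect_true(all(is.na(days[period %in% missing_days, rate])))
  }

  # hour-of-day profile recomputes from event level and conserves episodes
  hours <- history_view(fx$facts, "hour", transfusion = fx$pl$transfusion)
  expect_identical(unique(hours$period), sprintf("%02d", 0:23))
  expect_equal(sum(hours[measure == "consent", denominator]),
               nrow(fx$pl$transfusion))
  expect_error(history_view(fx$facts, "hour"), "transfusion")
})

test_that("dimension filters restrict every view consistently", {
  fx <- wh_fixture()
  w <- fx$pl$transfusion$ward[1L]
  sv <- status_view(fx$facts, "2021-12", filters = list(ward = w))
  expect_equal(sv[measure == "consent", denominator],
               nrow(fx$pl$transfusion[ward == w]))
  expect_error(status_view(fx$facts, "2021-12",
                           filters = list(postcode = "x")),
               "unknown filter")
})
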