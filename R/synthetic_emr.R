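# Synthetic EMR extract simulator.
#
# Generates ground-truth transfusion cohorts and emits them exactly the
# way the EMR extract delivers them: one long-format row per clinical
# event, never a pre-joined transfusion row. The simulator reproduces the
# structural defects the pipeline exists to handle - transfusions split
# across many records, missing completion records, superseded record
# versions via the UPDT_CNT counter, concurrent transfusions sharing a
# patient's observations - while keeping the intended truth alongside so
# every downstream stage can be verified without hospital data.
#
# Observation placement is contamination-free by construction: a row
# emitted for one scheduled interval falls inside no other interval's
# scoring window (hourly rows sit in the start-anchored window shrunk by
# one minute at shared boundaries and strictly before the true end; post
# rows sit past the last required hourly window). With no corrections and
# no concurrency the emitted rows therefore reproduce the ground-truth
# per-interval flags exactly.

.sim_hourly_max <- 3L
.sim_intervals <- c("BASELINE", "MIN15", "HOURLY", "POST")

#' Configuration for the synthetic cohort simulator
#'
#' Defaults describe a plausible audit month in a mid-size hospital
#' network: most encounters receive a single transfusion, transfusions
#' run 30-300 minutes, around 85% of scheduled observation intervals are
#' fully documented, and roughly one correction per twenty events arrives
#' later as a superseding version.
#'
#' @param n_encounters number of encounters (one patient each).
#' @param episodes_per_encounter_prob named probabilities over 1, 2 or 3
#'   transfusion episodes per encounter.
#' @param duration_minutes_range inclusive range of true transfusion
#'   durations, minutes.
#' @param p_obs_interval named probabilities, one per interval
#'   (`BASELINE`, `MIN15`, `HOURLY`, `POST`), that the interval is fully
#'   documented (all four vital-sign categories). The `HOURLY`
#'   probability applies independently to each required hourly
#'   subinterval.
#' @param p_consent probability a consent record exists.
#' @param p_compatibility probability a compatibility record exists.
#' @param p_completion_recorded probability the Complete record was
#'   documented.
#' @param p_concurrent probability a follow-on episode starts before the
#'   previous one completes (simultaneous transfusion).
#' @param p_correction probability an event later receives a superseding
#'   corrected version (used by [inject_corrections()]).
#' @param n_facilities,n_wards,n_medical_services dimension cardinality.
#' @param time_span length-2 character or POSIXct: earliest and latest
#'   episode start.
#' @param seed integer; a fixed seed makes the whole emitted extract
#'   byte-identical across runs.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_encounters = 150L,
                              episodes_per_encounter_prob = c(`1` = 0.7, `2` = 0.2, `3` = 0.1),
                              duration_minutes_range = c(30L, 300L),
                              p_obs_interval = c(BASELINE = 0.85, MIN15 = 0.85,
                                                 HOURLY = 0.85, POST = 0.85),
                              p_consent = 0.9,
                              p_compatibility = 0.9,
                              p_completion_recorded = 0.85,
                              p_concurrent = 0.1,
                              p_correction = 0.05,
                              n_facilities = 3L,
                              n_wards = 5L,
                              n_medical_services = 4L,
                              time_span = c("2021-12-01 00:00", "2021-12-31 23:59"),
                              seed = 1L) {
  # config files hand these over as lists; flatten before validating
  if (is.list(episodes_per_encounter_prob)) {
    episodes_per_encounter_prob <- unlist(episodes_per_encounter_prob)
  }
  if (is.list(duration_minutes_range)) {
    duration_minutes_range <- unlist(duration_minutes_range)
  }
  if (is.list(p_obs_interval)) p_obs_interval <- unlist(p_obs_interval)
  if (is.list(time_span)) time_span <- unlist(time_span)
  cfg <- list(
    n_encounters = n_encounters,
    episodes_per_encounter_prob = episodes_per_encounter_prob,
    duration_minutes_range = duration_minutes_range,
    p_obs_interval = p_obs_interval,
    p_consent = p_consent, p_compatibility = p_compatibility,
    p_completion_recorded = p_completion_recorded,
    p_concurrent = p_concurrent, p_correction = p_correction,
    n_facilities = n_facilities, n_wards = n_wards,
    n_medical_services = n_medical_services,
    time_span = time_span, seed = seed
  )
  cfg_error <- function(field, msg) {
    stop(sprintf("simulation_config: '%s' %s", field, msg), call. = FALSE)
  }
  if (!is.numeric(cfg$n_encounters) || length(cfg$n_encounters) != 1L ||
      is.na(cfg$n_encounters) || cfg$n_encounters < 1) {
    cfg_error("n_encounters", "must be a positive integer")
  }
  cfg$n_encounters <- as.integer(cfg$n_encounters)
  dist <- cfg$episodes_per_encounter_prob
  if (!setequal(names(dist), c("1", "2", "3")) || any(dist < 0) ||
      abs(sum(dist) - 1) > 1e-8) {
    cfg_error("episodes_per_encounter_prob",
              "must be probabilities over counts 1, 2, 3 summing to 1")
  }
  dr <- cfg$duration_minutes_range
  if (length(dr) != 2L || any(is.na(dr)) || dr[1L] < 30 || dr[2L] > 300 ||
      dr[1L] > dr[2L]) {
    cfg_error("duration_minutes_range",
              "must be an increasing range inside [30, 300] minutes")
  }
  cfg$duration_minutes_range <- as.integer(dr)
  pobs <- cfg$p_obs_interval
  if (!setequal(names(pobs), .sim_intervals)) {
    cfg_error("p_obs_interval", paste("needs probabilities named",
                                      paste(.sim_intervals, collapse = ", ")))
  }
  for (field in c("p_consent", "p_compatibility", "p_completion_recorded",
                  "p_concurrent", "p_correction")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      cfg_error(field, "must be a probability in [0, 1]")
    }
  }
  if (any(pobs < 0 | pobs > 1)) {
    cfg_error("p_obs_interval", "probabilities must lie in [0, 1]")
  }
  for (field in c("n_facilities", "n_wards", "n_medical_services")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1) {
      cfg_error(field, "must be a positive integer")
    }
    cfg[[field]] <- as.integer(v)
  }
  ts <- cfg$time_span
  if (length(ts) != 2L) cfg_error("time_span", "needs a start and an end")
  ts <- if (inherits(ts, "POSIXct")) trunc_minute(ts) else parse_event_time(ts)
  if (any(is.na(ts)) || ts[1L] >= ts[2L]) {
    cfg_error("time_span", "start must parse and precede end")
  }
  cfg$time_span <- ts
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    cfg_error("seed", "must be an integer")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> %d encounters, %s .. %s, seed %d\n",
              x$n_encounters, format_event_time(x$time_span[1L]),
              format_event_time(x$time_span[2L]), x$seed))
  invisible(x)
}

# observation source forms and value generators per category
.obs_forms <- list(
  PULSE = c("Peripheral Pulse Rate", "Heart Rate"),
  RESP_RATE = "Respiratory Rate",
  TEMPERATURE = c("Temperature Axillary", "Temperature Oesophageal",
                  "Temperature Oral", "Temperature Tympanic"),
  BLOOD_PRESSURE = c("Systolic Blood Pressure", "Diastolic Blood Pressure")
)

.obs_value <- function(category) {
  switch(category,
         PULSE = as.character(sample(55:110, 1L)),
         RESP_RATE = as.character(sample(10:24, 1L)),
         TEMPERATURE = sprintf("%.1f", runif(1L, 35.8, 37.8)),
         BLOOD_PRESSURE = as.character(sample(60:150, 1L)))
}

.products <- c("RBC", "Platelets", "FFP", "Cryoprecipitate")

#' Simulate a ground-truth transfusion cohort
#'
#' Draws encounters, episodes and their intended documentation, and emits
#' the corresponding raw long-format event rows (one row per clinical
#' event). Dimension columns are constant within an encounter. All rows
#' carry `updt_cnt = 1`; superseding versions come from
#' [inject_corrections()].
#'
#' @param config a [simulation_config()].
#' @return an object of class `ground_truth`: `episodes` (intended truth,
#'   one row per episode), `events` (emitted raw rows keyed back to
#'   episodes via `truth_episode_id`, plus the `extract_dt_tm` visibility
#'   time used for batching), and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  span_min <- as.integer(difftime(config$time_span[2L], config$time_span[1L],
                                  units = "mins"))
  ev_counter <- 0L
  next_key <- function() {
    ev_counter <<- ev_counter + 1L
    sprintf("EV-%06d", ev_counter)
  }
  ep_rows <- list()
  event_rows <- list()

  for (enc in seq_len(config$n_encounters)) {
    encounter_id <- sprintf("ENC-%05d", enc)
    patient_id <- sprintf("PAT-%05d", enc)
    facility <- sprintf("FAC-%d", sample.int(config$n_facilities, 1L))
    ward <- sprintf("WARD-%d", sample.int(config$n_wards, 1L))
    service <- sprintf("SVC-%d", sample.int(config$n_medical_services, 1L))

    n_ep <- sample(1:3, 1L, prob = config$episodes_per_encounter_prob)
    prev_start <- prev_end <- NULL
    for (k in seq_len(n_ep)) {
      dur <- sample(seq(config$duration_minutes_range[1L],
                        config$duration_minutes_range[2L]), 1L)
      if (k == 1L) {
        start <- config$time_span[1L] + .mins(sample.int(span_min, 1L) - 1L)
        concurrent <- FALSE
      } else {
        prev_dur <- as.integer(difftime(prev_end, prev_start, units = "mins"))
        concurrent <- runif(1L) < config$p_concurrent && prev_dur > 20L
        start <- if (concurrent) {
          prev_start + .mins(sample(seq(10L, prev_dur - 10L), 1L))
        } else {
          prev_end + .mins(sample(180:720, 1L))
        }
      }
      end <- start + .mins(dur)
      prev_start <- start
      prev_end <- end
      truth_id <- sprintf("T-%s-%d", encounter_id, k)
      product <- sample(.products, 1L)

      out <- simulate_episode_events(
        truth_id, encounter_id, patient_id, facility, ward, service,
        start, end, dur, product, config, next_key)

      ep_rows[[length(ep_rows) + 1L]] <- cbind(
        data.table(truth_episode_id = truth_id, encounter_id = encounter_id,
                   patient_id = patient_id, facility = facility, ward = ward,
                   medical_service = service, start_time = start,
                   end_time = end, duration_min = dur,
                   product_type = product, concurrent = concurrent),
        out$flags)
      event_rows[[length(event_rows) + 1L]] <- out$events
    }
  }

  events <- rbindlist(event_rows)
  events[, row_id := sprintf("R-%06d", seq_len(.N))]
  events[, `:=`(updt_cnt = 1L, batch_id = NA_character_,
                extract_dt_tm = event_dt_tm)]
  setcolorder(events, c(names(empty_records()), "truth_episode_id",
                        "extract_dt_tm"))
  structure(list(episodes = rbindlist(ep_rows), events = events[],
                 config = config),
            class = "ground_truth")
}

# emit the event rows of one episode and its intended documentation flags
simulate_episode_events <- function(truth_id, encounter_id, patient_id,
                                    facility, ward, service, start, end,
                                    dur, product, config, next_key) {
  p <- config$p_obs_interval
  add_name <- character(); add_val <- character(); add_off <- integer()

  place_interval <- function(offsets) {
    # one row per category, a random source form, a uniform minute offset
    for (cat in names(.obs_forms)) {
      form <- .obs_forms[[cat]][sample.int(length(.obs_forms[[cat]]), 1L)]
      add_name <<- c(add_name, form)
      add_val <<- c(add_val, .obs_value(cat))
      add_off <<- c(add_off, if (length(offsets) == 1L) offsets
                             else sample(offsets, 1L))
    }
  }

  doc_baseline <- runif(1L) < p[["BASELINE"]]
  if (doc_baseline) place_interval(-60:5)
  doc_min15 <- runif(1L) < p[["MIN15"]]
  if (doc_min15) place_interval(10:20)

  required <- which(dur > 60L * seq_len(.sim_hourly_max))
  doc_hourly <- rep(NA, .sim_hourly_max)
  for (k in required) {
    doc_hourly[k] <- runif(1L) < p[["HOURLY"]]
    if (doc_hourly[k]) {
      # start-anchored window shrunk 1 min at shared boundaries, kept
      # strictly before the true end so it cannot stray into POST
      place_interval(seq(60L * k - 19L, min(60L * k + 19L, dur - 1L)))
    }
  }
  doc_post <- runif(1L) < p[["POST"]]
  if (doc_post) {
    last_req <- if (length(required)) max(required) else 0L
    lo <- max(dur, 60L * last_req + 41L)
    place_interval(seq(lo, dur + 60L))
  }

  consent_given <- runif(1L) < config$p_consent
  compatibility_given <- runif(1L) < config$p_compatibility
  completion_recorded <- runif(1L) < config$p_completion_recorded

  name <- c("Transfusion Initiated",
            if (completion_recorded) "Transfusion Completed",
            if (consent_given) "Blood Product Consent",
            if (compatibility_given) "Blood Compatibility Check",
            add_name)
  val <- c(product,
           if (completion_recorded) product,
           if (consent_given) "Consent obtained",
           if (compatibility_given) "Compatible",
           add_val)
  off <- c(0L,
           if (completion_recorded) dur,
           if (consent_given) -sample(30:720, 1L),
           if (compatibility_given) -sample(5:60, 1L),
           add_off)

  events <- data.table(
    row_id = NA_character_,
    event_key = vapply(seq_along(name), function(i) next_key(), character(1L)),
    patient_id = patient_id, encounter_id = encounter_id,
    result_name = name, result_value = val,
    event_dt_tm = start + .mins(off),
    updt_cnt = 1L, facility = facility, ward = ward,
    medical_service = service, batch_id = NA_character_,
    truth_episode_id = truth_id
  )

  flags <- data.table(
    consent_given = consent_given,
    compatibility_given = compatibility_given,
    completion_recorded = completion_recorded,
    doc_baseline = doc_baseline, doc_min15 = doc_min15,
    doc_hourly_1 = doc_hourly[1L], doc_hourly_2 = doc_hourly[2L],
    doc_hourly_3 = doc_hourly[3L], doc_post = doc_post
  )
  list(events = events, flags = flags)
}

#' Inject superseding record versions
#'
#' Emulates retrospective correction in the EMR: the original row is kept
#' and an additional row appears with the same logical event key, the
#' version counter incremented, a fresh physical row identifier, and a
#' corrected value or timestamp. Initiate corrections move the start
#' earlier, Complete corrections move the end later, any other event gets
#' a corrected value. The ground truth is updated to the corrected
#' values; the correction's `extract_dt_tm` (when it becomes visible to
#' extraction) lies 10 minutes to 2 days after the original event, so a
#' correction row may land in a later batch than the row it supersedes.
#'
#' @param truth a `ground_truth` from [simulate_cohort()].
#' @param p_correction probability each original event is corrected;
#'   defaults to the simulation config's value.
#' @param seed RNG seed for the injection (distinct from the cohort
#'   seed so that correcting is reproducible given the same truth).
#' @return the updated `ground_truth`, correction rows appended.
#' @export
inject_corrections <- function(truth,
                               p_correction = truth$config$p_correction,
                               seed = truth$config$seed + 1000L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!is.numeric(p_correction) || length(p_correction) != 1L ||
      is.na(p_correction) || p_correction < 0 || p_correction > 1) {
    stop("inject_corrections: 'p_correction' must be a probability in [0, 1]",
         call. = FALSE)
  }
  if (p_correction == 0) return(truth)
  with_seed(seed, inject_corrections_impl(truth, p_correction))
}

inject_corrections_impl <- function(truth, p_correction) {
  ev <- truth$events
  episodes <- copy(truth$episodes)
  originals <- which(ev$updt_cnt == 1L)
  sel <- originals[runif(length(originals)) < p_correction]
  if (!length(sel)) return(truth)

  role <- classify(ev$result_name[sel])$role
  corr <- copy(ev[sel])
  corr[, `:=`(row_id = sprintf("RC-%06d", seq_len(.N)),
              updt_cnt = updt_cnt + 1L)]

  evt <- corr$event_dt_tm
  ext <- corr$extract_dt_tm
  val <- corr$result_value
  for (i in seq_along(sel)) {
    ext[i] <- evt[i] + .mins(sample(10:2880, 1L))
    if (role[i] == "INITIATE") {
      shift <- .mins(sample(5:45, 1L))
      evt[i] <- evt[i] - shift
      tid <- corr$truth_episode_id[i]
      episodes[truth_episode_id == tid,
               `:=`(start_time = start_time - shift,
                    duration_min = duration_min + as.integer(shift / 60))]
    } else if (role[i] == "COMPLETE") {
      shift <- .mins(sample(5:45, 1L))
      evt[i] <- evt[i] + shift
      tid <- corr$truth_episode_id[i]
      episodes[truth_episode_id == tid,
               `:=`(end_time = end_time + shift,
                    duration_min = duration_min + as.integer(shift / 60))]
    } else {
      num <- suppressWarnings(as.numeric(val[i]))
      val[i] <- if (!is.na(num)) {
        sprintf("%.1f", num + sample(c(-2, -1, 1, 2), 1L))
      } else {
        paste0(val[i], " (amended)")
      }
    }
  }
  corr[, `:=`(event_dt_tm = evt, extract_dt_tm = ext, result_value = val)]
  events <- rbind(ev, corr)
  setorderv(events, c("extract_dt_tm", "row_id"))
  structure(list(episodes = episodes[], events = events[],
                 config = truth$config),
            class = "ground_truth")
}

#' Emit a cohort as raw extract batch files
#'
#' Rows are assigned to batches by the time they became visible to
#' extraction (`extract_dt_tm`): a correction row lands in the batch of
#' its correction time, which may be later than the original row's batch.
#' The concatenation of all batches is exactly the full row set, whatever
#' the batching frequency.
#'
#' @param truth a `ground_truth`.
#' @param batching `"single"`, `"monthly"`, `"daily"` or `"hourly"`.
#' @param dir output directory (created if needed).
#' @param column_map the [column_map()] defining the extract header.
#' @return character vector of file paths, in chronological batch order.
#' @export
emit_extracts <- function(truth, batching = c("single", "monthly", "daily", "hourly"),
                          dir, column_map = bloodcdw::column_map()) {
  stopifnot(inherits(truth, "ground_truth"))
  if (nrow(truth$events) == 0L) stop("emit_extracts: cohort is empty", call. = FALSE)
  batching <- match.arg(batching)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- copy(truth$events)
  key <- switch(batching,
                single = rep("all", nrow(ev)),
                monthly = format(ev$extract_dt_tm, "%Y-%m", tz = "UTC"),
                daily = format(ev$extract_dt_tm, "%Y-%m-%d", tz = "UTC"),
                hourly = format(ev$extract_dt_tm, "%Y-%m-%dT%H", tz = "UTC"))
  ev[, batch_id := paste0("extract-", key)]
  setorderv(ev, c("extract_dt_tm", "row_id"))
  paths <- character()
  for (b in sort(unique(ev$batch_id))) {
    path <- file.path(dir, paste0(b, ".csv"))
    write_extract(ev[batch_id == b], path, column_map)
    paths <- c(paths, path)
  }
  paths
}

#' Write the ground truth for test-harness use
#'
#' Two CSVs (`ground_truth_episodes.csv`, `ground_truth_events.csv`) with
#' the intended episodes and the emitted rows keyed back to them. This is
#' harness metadata, not part of the extract interface.
#'
#' @param truth a `ground_truth`.
#' @param dir output directory.
#' @return invisible character vector of the two paths.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  eps <- copy(truth$episodes)
  eps[, `:=`(start_time = format_event_time(start_time),
             end_time = format_event_time(end_time))]
  ev <- copy(truth$events)
  ev[, `:=`(event_dt_tm = format_event_time(event_dt_tm),
            extract_dt_tm = format_event_time(extract_dt_tm))]
  p1 <- file.path(dir, "ground_truth_episodes.csv")
  p2 <- file.path(dir, "ground_truth_events.csv")
  fwrite(eps, p1, quote = TRUE, na = "")
  fwrite(ev, p2, quote = TRUE, na = "")
  invisible(c(p1, p2))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d episodes across %d encounters, %d event rows (seed %d)\n",
              nrow(x$episodes), length(unique(x$episodes$encounter_id)),
              nrow(x$events), x$config$seed))
  invisible(x)
}
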