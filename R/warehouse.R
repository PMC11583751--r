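# The two-granularity warehouse.
#
# Event granularity: the TRANSFUSION table, one row per reconstructed
# episode with its precomputed compliance flags. Daily granularity: the
# TRANSFUSION_DAILY_FACT table, counts per (date, facility, ward, medical
# service). The fact table exists purely for query speed - every
# statistic it yields must equal the same statistic recomputed from the
# event-granularity table.

.fact_dims <- c("facility", "ward", "medical_service")

# numerator / denominator fact columns per measure
.measure_cols <- list(
  consent = c("n_consent_pass", "n_transfusions"),
  compatibility = c("n_compatibility_pass", "n_transfusions"),
  completion = c("n_completion_documented", "n_transfusions"),
  baseline = c("n_baseline_pass", "n_transfusions"),
  min15 = c("n_min15_pass", "n_transfusions"),
  hourly = c("n_hourly_pass", "n_transfusions"),
  post = c("n_post_pass", "n_post_assessable")
)

#' Join episodes with their compliance flags (the TRANSFUSION table)
#'
#' @param recon a `reconstruction`.
#' @param compliance the matching table from [evaluate_compliance()].
#' @return `data.table`, one row per episode, episode fields plus
#'   compliance flags, ordered by `episode_id`.
#' @export
transfusion_table <- function(recon, compliance) {
  comp <- as.data.table(compliance)
  comp <- comp[, setdiff(names(comp), "ambiguity_flag"), with = FALSE]
  out <- merge(recon$episodes, comp, by = "episode_id", all.x = TRUE)
  setorderv(out, "episode_id")
  out[]
}

count_flags <- function() {
  # grouped-count expression shared by every aggregation level
  quote(list(
    n_transfusions = .N,
    n_consent_pass = sum(consent_documented),
    n_compatibility_pass = sum(compatibility_documented),
    n_completion_documented = sum(completion_documented),
    n_baseline_pass = sum(baseline_pass),
    n_min15_pass = sum(min15_pass),
    n_hourly_pass = sum(hourly_pass),
    n_post_pass = sum(post_pass == "PASS"),
    n_post_assessable = sum(post_pass != "NOT_ASSESSABLE")
  ))
}

#' Aggregate the TRANSFUSION table into daily facts
#'
#' Grouping key: calendar date of the episode start (local time) by
#' facility, ward and medical service. Output ordering is deterministic.
#'
#' @param transfusion the event-granularity table from
#'   [transfusion_table()].
#' @return the TRANSFUSION_DAILY_FACT `data.table`.
#' @export
aggregate_daily <- function(transfusion) {
  tf <- as.data.table(transfusion)
  if (nrow(tf) == 0L) return(empty_daily_fact())
  facts <- tf[, eval(count_flags()),
              by = list(date = as.Date(start_time, tz = "UTC"),
                        facility, ward, medical_service)]
  setorderv(facts, c("date", .fact_dims))
  facts[]
}

empty_daily_fact <- function() {
  data.table(
    date = as.Date(character()), facility = character(), ward = character(),
    medical_service = character(), n_transfusions = integer(),
    n_consent_pass = integer(), n_compatibility_pass = integer(),
    n_completion_documented = integer(), n_baseline_pass = integer(),
    n_min15_pass = integer(), n_hourly_pass = integer(),
    n_post_pass = integer(), n_post_assessable = integer()
  )
}

filter_facts <- function(facts, filters = list()) {
  bad <- setdiff(names(filters), .fact_dims)
  if (length(bad)) {
    stop("unknown filter dimension(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (d in names(filters)) {
    facts <- facts[facts[[d]] %chin% filters[[d]]]
  }
  facts
}

#' How many transfusions lack a consent record in a month?
#'
#' The first of the warehouse's reference analytical queries, answered
#' from the daily fact table alone.
#'
#' @param facts the daily fact table.
#' @param month calendar month as `"YYYY-MM"`.
#' @param filters optional named list restricting facility / ward /
#'   medical_service.
#' @return integer count; 0 with a warning when the month has no data.
#' @export
query_missing_consents <- function(facts, month, filters = list()) {
  stopifnot(grepl("^\\d{4}-\\d{2}$", month))
  facts <- filter_facts(as.data.table(facts), filters)
  sub <- facts[format(date, "%Y-%m") == month]
  if (nrow(sub) == 0L) {
    warning("no fact rows for month ", month)
    return(0L)
  }
  as.integer(sum(sub$n_transfusions - sub$n_consent_pass))
}

#' Rank dimension values by compliance rate, lowest first
#'
#' The second reference query: which facilities (or wards, or medical
#' services) have the lowest rate on a measure in a period. Values with a
#' zero denominator cannot be ranked; they are excluded from the ranking
#' and listed in the `"zero_denominator"` attribute.
#'
#' @param facts the daily fact table.
#' @param measure one of [cdw_measures()].
#' @param dimension `"facility"`, `"ward"` or `"medical_service"`.
#' @param period optional `"YYYY"` or `"YYYY-MM"` restriction.
#' @return `data.table` of dimension value, numerator, denominator and
#'   rate, ascending by rate (ties alphabetical).
#' @export
query_lowest_dimension <- function(facts, measure, dimension,
                                   period = NULL) {
  if (!measure %in% names(.measure_cols)) {
    stop("unknown measure '", measure, "'; expected one of ",
         paste(names(.measure_cols), collapse = ", "), call. = FALSE)
  }
  if (!dimension %in% .fact_dims) {
    stop("unknown dimension '", dimension, "'; expected one of ",
         paste(.fact_dims, collapse = ", "), call. = FALSE)
  }
  facts <- as.data.table(facts)
  if (!is.null(period)) {
    stopifnot(grepl("^\\d{4}(-\\d{2})?$", period))
    facts <- facts[startsWith(format(date, "%Y-%m"), period)]
  }
  cols <- .measure_cols[[measure]]
  agg <- facts[, list(numerator = sum(.SD[[cols[1L]]]),
                      denominator = sum(.SD[[cols[2L]]])),
               by = c(dimension), .SDcols = cols]
  zero <- agg[denominator == 0L][[dimension]]
  agg <- agg[denominator > 0L]
  agg[, rate := numerator / denominator]
  setorderv(agg, c("rate", dimension))
  setattr(agg, "zero_denominator", zero)
  agg[]
}

#' Status view: one month's rates against their targets
#'
#' Mirrors the dashboard's status tab: for the selected calendar month
#' (episode start, local time) and optional facility / ward / medical
#' service filters, each measure's numerator, denominator, rate, target
#' and whether the target is met. A zero denominator leaves the rate and
#' `met` undefined (`NA`) and sets `undefined = TRUE` rather than
#' reporting a spurious 0% or 100%.
#'
#' @param facts the daily fact table.
#' @param month `"YYYY-MM"`.
#' @param filters optional named list over facility / ward /
#'   medical_service.
#' @param targets named targets as from [measure_targets()] (default: 80%
#'   for every measure).
#' @return `data.table` with one row per measure; the month and filters
#'   are attached as attributes `"period"` and `"filters"`.
#' @export
status_view <- function(facts, month, filters = list(),
                        targets = measure_targets()) {
  stopifnot(grepl("^\\d{4}-\\d{2}$", month))
  facts <- filter_facts(as.data.table(facts), filters)
  sub <- facts[format(date, "%Y-%m") == month]
  rows <- lapply(cdw_measures(), function(m) {
    cols <- .measure_cols[[m]]
    num <- sum(sub[[cols[1L]]])
    den <- sum(sub[[cols[2L]]])
    data.table(measure = m, numerator = as.integer(num),
               denominator = as.integer(den),
               rate = if (den > 0) num / den else NA_real_,
               target = unname(targets[[m]]),
               met = if (den > 0) (num / den) >= targets[[m]] else NA,
               undefined = den == 0)
  })
  out <- rbindlist(rows)
  setattr(out, "period", month)
  setattr(out, "filters", filters)
  out[]
}

#' History view: per-measure time series
#'
#' Mirrors the dashboard's history tab. For `year`, `month` and `day`
#' granularity the series comes from the daily fact table and covers the
#' observed span contiguously — periods without transfusions appear with
#' zero denominators rather than being skipped. `hour` granularity is an
#' hour-of-day profile (00-23) and is recomputed from the
#' event-granularity TRANSFUSION table, which must then be supplied,
#' since daily facts cannot resolve hours.
#'
#' @param facts the daily fact table.
#' @param granularity `"year"`, `"month"`, `"day"` or `"hour"`.
#' @param filters optional named list over facility / ward /
#'   medical_service.
#' @param transfusion the event-granularity table; required for
#'   `granularity = "hour"`.
#' @return tidy `data.table`: `period`, `measure`, `numerator`,
#'   `denominator`, `rate` (NA where the denominator is zero).
#' @export
history_view <- function(facts, granularity = c("month", "year", "day", "hour"),
                         filters = list(), transfusion = NULL) {
  granularity <- match.arg(granularity)

  if (granularity == "hour") {
    if (is.null(transfusion)) {
      stop("hour granularity is recomputed from the event-granularity table; supply 'transfusion'",
           call. = FALSE)
    }
    tf <- filter_facts(as.data.table(transfusion), filters)
    if (nrow(tf)) {
      hf <- tf[, eval(count_flags()),
               by = list(period = format(start_time, "%H", tz = "UTC"))]
    } else {
      hf <- data.table()
    }
    all_periods <- sprintf("%02d", 0:23)
    return(series_from_counts(hf, all_periods))
  }

  facts <- filter_facts(as.data.table(facts), filters)
  if (nrow(facts) == 0L) {
    return(data.table(period = character(), measure = character(),
                      numerator = integer(), denominator = integer(),
                      rate = numeric()))
  }
  fmt <- switch(granularity, year = "%Y", month = "%Y-%m", day = "%Y-%m-%d")
  pf <- facts[, eval(count_flags_sum()), by = list(period = format(date, fmt))]
  span <- range(facts$date)
  all_periods <- switch(
    granularity,
    year = as.character(seq(as.integer(format(span[1L], "%Y")),
                            as.integer(format(span[2L], "%Y")))),
    month = format(seq(as.Date(cut(span[1L], "month")),
                       as.Date(cut(span[2L], "month")), by = "month"),
                   "%Y-%m"),
    day = format(seq(span[1L], span[2L], by = "day"), "%Y-%m-%d")
  )
  series_from_counts(pf, all_periods)
}

count_flags_sum <- function() {
  # re-aggregate fact counts (already counted once per day)
  quote(list(
    n_transfusions = sum(n_transfusions),
    n_consent_pass = sum(n_consent_pass),
    n_compatibility_pass = sum(n_compatibility_pass),
    n_completion_documented = sum(n_completion_documented),
    n_baseline_pass = sum(n_baseline_pass),
    n_min15_pass = sum(n_min15_pass),
    n_hourly_pass = sum(n_hourly_pass),
    n_post_pass = sum(n_post_pass),
    n_post_assessable = sum(n_post_assessable)
  ))
}

series_from_counts <- function(counts, all_periods) {
  rows <- lapply(all_periods, function(p) {
    row <- if (nrow(counts)) counts[period == p] else counts
    rbindlist(lapply(cdw_measures(), function(m) {
      cols <- .measure_cols[[m]]
      num <- if (nrow(row)) as.integer(row[[cols[1L]]]) else 0L
      den <- if (nrow(row)) as.integer(row[[cols[2L]]]) else 0L
      data.table(period = p, measure = m, numerator = num,
                 denominator = den,
                 rate = if (den > 0) num / den else NA_real_)
    }))
  })
  rbindlist(rows)
}
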