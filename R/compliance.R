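# Compliance scoring against the four-interval observation schedule.
#
# Each reconstructed episode is scored on seven documentation measures:
# consent, compatibility, completion, and the four vital-sign intervals
# (baseline, 15-minute, hourly, post). An interval passes when at least
# one attributed observation of each of the four categories (pulse,
# respiratory rate, temperature, blood pressure) falls inside its window
# set. All interval bounds are closed: the policy's phrasing is inclusive
# ("up to 5 mins after"), so a reading on the boundary minute counts.
#
# Hourly windows carry two kinds of anchor: the transfusion start and the
# 15-minute observation. Every attributed observation inside the
# 15-minute window contributes an anchor; the hour-k window set is the
# union of [anchor + 60k - grace, anchor + 60k + grace] over all anchors.
# Using every 15-minute observation (not only the earliest) keeps scoring
# monotone - documenting an extra reading can never turn a pass into a
# fail - and is the most permissive reading of "in relation to either the
# start of the transfusion or the 15-minute observation".

#' Compute the interval window sets for an episode
#'
#' @param start_time episode start (the Initiate time).
#' @param end_time episode end (the Complete time), or `NA`/`NULL` when
#'   no completion was documented; the POST window then does not exist.
#' @param policy a [window_policy()].
#' @param obs_times attributed observation timestamps of the episode;
#'   those inside the 15-minute window anchor additional hourly windows.
#' @return named list: `BASELINE`, `MIN15`, `HOURLY_1` ..
#'   `HOURLY_<max>`, and `POST` when the end is known. Each element is a
#'   two-column matrix of closed `[lo, hi]` bounds in seconds (POSIXct
#'   numeric); hourly elements may hold several rows, one per anchor.
#' @export
interval_windows <- function(start_time, end_time = NULL,
                             policy = window_policy(), obs_times = NULL) {
  s <- as.numeric(start_time)
  stopifnot(length(s) == 1L, !is.na(s))
  e <- if (is.null(end_time) || is.na(end_time)) NA_real_ else as.numeric(end_time)
  g <- .mins(policy$hourly_grace_min)

  win <- list(
    BASELINE = matrix(c(s - .mins(policy$baseline_before_min),
                        s + .mins(policy$baseline_after_min)), ncol = 2L),
    MIN15 = matrix(c(s + .mins(policy$t15_nominal_min - policy$t15_grace_min),
                     s + .mins(policy$t15_nominal_min + policy$t15_grace_min)),
                   ncol = 2L)
  )

  ot <- as.numeric(obs_times)
  anchors <- s
  if (length(ot)) {
    t15 <- sort(unique(ot[ot >= win$MIN15[1L, 1L] & ot <= win$MIN15[1L, 2L]]))
    anchors <- c(anchors, t15)
  }
  for (k in seq_len(policy$hourly_max_subintervals)) {
    ctr <- anchors + .mins(60L * k)
    win[[paste0("HOURLY_", k)]] <- cbind(ctr - g, ctr + g)
  }
  if (!is.na(e)) {
    win$POST <- matrix(c(e, e + .mins(policy$post_window_min)), ncol = 2L)
  }
  win
}

#' Which hourly subintervals does an episode owe?
#'
#' Hourly observations are owed only while the transfusion is running: if
#' it completes before the k-th hour, the k-th observation is not
#' required. When no completion record exists the policy decides:
#' `ASSUME_MAX` requires every subinterval up to the maximum (a missing
#' completion does not excuse missing observations), `CENSOR` requires
#' subinterval k only when the episode's attributed documentation
#' demonstrably extends past the k-th window.
#'
#' @param start_time,end_time episode bounds (`end_time` `NA`/`NULL` when
#'   unknown).
#' @param policy a [window_policy()].
#' @param last_event_time latest attributed observation time, used only
#'   under `CENSOR` with an unknown end.
#' @return integer vector, subset of `1:hourly_max_subintervals`.
#' @export
required_hourly_subintervals <- function(start_time, end_time = NULL,
                                         policy = window_policy(),
                                         last_event_time = NULL) {
  ks <- seq_len(policy$hourly_max_subintervals)
  s <- as.numeric(start_time)
  e <- if (is.null(end_time) || is.na(end_time)) NA_real_ else as.numeric(end_time)
  if (!is.na(e)) {
    return(ks[e > s + .mins(60L * ks)])
  }
  if (policy$open_episode_policy == "ASSUME_MAX") {
    return(ks)
  }
  if (is.null(last_event_time) || !length(last_event_time) ||
      all(is.na(last_event_time))) {
    return(integer())
  }
  last <- max(as.numeric(last_event_time), na.rm = TRUE)
  ks[s + .mins(60L * ks + policy$hourly_grace_min) <= last]
}

#' Which vital-sign categories are documented inside a window set?
#'
#' @param observations attribution table with columns `category` and
#'   `obs_time` (as produced by [build_episodes()]).
#' @param windows two-column matrix of closed `[lo, hi]` bounds (one
#'   element of [interval_windows()]).
#' @return character vector, the subset of the four categories with at
#'   least one observation inside any window of the set.
#' @export
categories_present <- function(observations, windows) {
  if (is.null(windows) || NROW(observations) == 0L) return(character())
  t <- as.numeric(observations$obs_time)
  inside <- rep(FALSE, length(t))
  for (r in seq_len(nrow(windows))) {
    inside <- inside | (t >= windows[r, 1L] & t <= windows[r, 2L])
  }
  intersect(.categories, unique(observations$category[inside]))
}

#' Score one episode against every documentation measure
#'
#' @param episode one-row episode table from [build_episodes()].
#' @param observations the episode's attributed observations (rows of the
#'   reconstruction's `observations` table for this episode).
#' @param policy a [window_policy()].
#' @return one-row `data.table`: documentation flags for consent,
#'   compatibility and completion; pass flags for baseline, 15-minute and
#'   hourly intervals; `hourly_detail` (per-subinterval
#'   `REQUIRED_PASS` / `REQUIRED_FAIL` / `NOT_REQUIRED`, `;`-separated);
#'   `post_pass` (`PASS` / `FAIL` / `NOT_ASSESSABLE` — the latter exactly
#'   when no completion record exists); and the matching ambiguity flag.
#' @export
evaluate_episode <- function(episode, observations = empty_observations(),
                             policy = window_policy()) {
  stopifnot(nrow(episode) == 1L)
  obs <- as.data.table(observations)
  win <- interval_windows(episode$start_time, episode$end_time, policy,
                          obs_times = obs$obs_time)
  all4 <- function(w) length(categories_present(obs, w)) == length(.categories)

  completion <- identical(episode$status, "CLOSED") && !is.na(episode$end_time)
  req <- required_hourly_subintervals(
    episode$start_time, episode$end_time, policy,
    last_event_time = if (nrow(obs)) max(obs$obs_time) else NULL)

  hk <- seq_len(policy$hourly_max_subintervals)
  hstat <- vapply(hk, function(k) {
    if (!k %in% req) return("NOT_REQUIRED")
    if (all4(win[[paste0("HOURLY_", k)]])) "REQUIRED_PASS" else "REQUIRED_FAIL"
  }, character(1L))

  data.table(
    episode_id = episode$episode_id,
    consent_documented = !is.na(episode$consent_key),
    compatibility_documented = !is.na(episode$compatibility_key),
    completion_documented = completion,
    baseline_pass = all4(win$BASELINE),
    min15_pass = all4(win$MIN15),
    hourly_pass = !any(hstat == "REQUIRED_FAIL"),
    hourly_detail = paste(hstat, collapse = ";"),
    post_pass = if (!completion) "NOT_ASSESSABLE"
                else if (all4(win$POST)) "PASS" else "FAIL",
    ambiguity_flag = isTRUE(episode$ambiguity_flag)
  )
}

#' Score every episode of a reconstruction
#'
#' @param recon a `reconstruction` from [build_episodes()].
#' @param policy a [window_policy()].
#' @return `data.table`, one row per episode (see [evaluate_episode()]).
#' @export
evaluate_compliance <- function(recon, policy = window_policy()) {
  eps <- recon$episodes
  if (nrow(eps) == 0L) return(empty_compliance())
  obs_split <- split(recon$observations, by = "episode_id", sorted = TRUE)
  rows <- lapply(seq_len(nrow(eps)), function(i) {
    ep <- eps[i]
    evaluate_episode(ep, obs_split[[ep$episode_id]] %||% empty_observations(),
                     policy)
  })
  out <- rbindlist(rows)
  setorderv(out, "episode_id")
  out[]
}

empty_compliance <- function() {
  data.table(
    episode_id = character(), consent_documented = logical(),
    compatibility_documented = logical(), completion_documented = logical(),
    baseline_pass = logical(), min15_pass = logical(),
    hourly_pass = logical(), hourly_detail = character(),
    post_pass = character(), ambiguity_flag = logical()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
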