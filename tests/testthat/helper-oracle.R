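# Brute-force compliance oracle.
#
# An independent re-derivation of the interval scoring: everything is
# computed in whole minutes relative to the episode start, with explicit
# nested loops over observations x windows. Deliberately shares no code
# with the package's evaluator.

oracle_windows <- function(start, end, obs_min, obs_cat, policy) {
  # returns a named list of lists of c(lo, hi) minute pairs
  w <- list()
  w$BASELINE <- list(c(-policy$baseline_before_min, policy$baseline_after_min))
  m15 <- c(policy$t15_nominal_min - policy$t15_grace_min,
           policy$t15_nominal_min + policy$t15_grace_min)
  w$MIN15 <- list(m15)
  anchors <- 0
  for (t in sort(unique(obs_min))) {
    if (t >= m15[1] && t <= m15[2]) anchors <- c(anchors, t)
  }
  for (k in seq_len(policy$hourly_max_subintervals)) {
    wk <- list()
    for (a in anchors) {
      wk[[length(wk) + 1]] <- c(a + 60 * k - policy$hourly_grace_min,
                                a + 60 * k + policy$hourly_grace_min)
    }
    w[[paste0("HOURLY_", k)]] <- wk
  }
  if (!is.na(end)) {
    w$POST <- list(c(end, end + policy$post_window_min))
  }
  w
}

oracle_cats_in <- function(windows, obs_min, obs_cat) {
  present <- character()
  for (i in seq_along(obs_min)) {
    for (win in windows) {
      if (obs_min[i] >= win[1] && obs_min[i] <= win[2]) {
        present <- union(present, obs_cat[i])
        break
      }
    }
  }
  present
}

# start/end: POSIXct (end NA when unknown); obs: data.frame with obs_time,
# category. Returns the same flags as evaluate_episode.
oracle_evaluate <- function(start, end, obs, policy = window_policy()) {
  end_min <- if (is.null(end) || is.na(end)) {
    NA_real_
  } else {
    as.numeric(difftime(end, start, units = "mins"))
  }
  obs_min <- if (NROW(obs)) {
    as.numeric(difftime(obs$obs_time, start, units = "mins"))
  } else {
    numeric()
  }
  obs_cat <- if (NROW(obs)) obs$category else character()
  w <- oracle_windows(0, end_min, obs_min, obs_cat, policy)
  all4 <- function(wins) {
    length(oracle_cats_in(wins, obs_min, obs_cat)) == 4
  }

  kmax <- policy$hourly_max_subintervals
  required <- logical(kmax)
  for (k in seq_len(kmax)) {
    if (!is.na(end_min)) {
      required[k] <- end_min > 60 * k
    } else if (policy$open_episode_policy == "ASSUME_MAX") {
      required[k] <- TRUE
    } else {
      required[k] <- length(obs_min) > 0 &&
        60 * k + policy$hourly_grace_min <= max(obs_min)
    }
  }
  hstat <- character(kmax)
  for (k in seq_len(kmax)) {
    hstat[k] <- if (!required[k]) {
      "NOT_REQUIRED"
    } else if (all4(w[[paste0("HOURLY_", k)]])) {
      "REQUIRED_PASS"
    } else {
      "REQUIRED_FAIL"
    }
  }
  list(
    baseline_pass = all4(w$BASELINE),
    min15_pass = all4(w$MIN15),
    hourly_detail = hstat,
    hourly_pass = !any(hstat == "REQUIRED_FAIL"),
    post_pass = if (is.na(end_min)) "NOT_ASSESSABLE"
                else if (all4(w$POST)) "PASS" else "FAIL"
  )
}

# compare package evaluation with the oracle over a whole reconstruction
oracle_agrees <- function(recon, comp, policy = window_policy()) {
  eps <- as.data.frame(recon$episodes)
  cmpdf <- as.data.frame(comp)
  row <- match(eps$episode_id, cmpdf$episode_id)
  obs_by_ep <- split(as.data.frame(recon$observations),
                     recon$observations$episode_id)
  for (i in seq_len(nrow(eps))) {
    o <- obs_by_ep[[eps$episode_id[i]]]
    want <- oracle_evaluate(eps$start_time[i], eps$end_time[i], o, policy)
    got <- cmpdf[row[i], ]
    if (got$baseline_pass != want$baseline_pass ||
        got$min15_pass != want$min15_pass ||
        got$hourly_pass != want$hourly_pass ||
        got$hourly_detail != paste(want$hourly_detail, collapse = ";") ||
        got$post_pass != want$post_pass) {
      return(eps$episode_id[i])
    }
  }
  TRUE
}
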