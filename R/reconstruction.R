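# Episode reconstruction.
#
# A transfusion exists in the extract only as scattered clinical events:
# the Initiate row is the sole marker that a transfusion began, and every
# other row (Complete, consent, compatibility, vital-sign observations)
# must be correlated back to it by encounter and time. Matching follows
# the latest-preceding-unmatched rule: a Complete closes the most recent
# Initiate of the same encounter at or before it that is still open. With
# simultaneous transfusions that rule is a heuristic, so an episode whose
# Complete had more than one candidate Initiate carries an ambiguity flag.

.episode_cols <- c("episode_id", "encounter_id", "patient_id",
                   "initiate_key", "complete_key", "start_time", "end_time",
                   "consent_key", "compatibility_key", "product_type",
                   "facility", "ward", "medical_service", "status",
                   "ambiguity_flag")

empty_episodes <- local({
  tmpl <- NULL
  function() {
    if (is.null(tmpl)) {
      tmpl <<- data.table(
        episode_id = character(), encounter_id = character(),
        patient_id = character(), initiate_key = character(),
        complete_key = character(),
        start_time = as.POSIXct(character(), tz = "UTC"),
        end_time = as.POSIXct(character(), tz = "UTC"),
        consent_key = character(), compatibility_key = character(),
        product_type = character(), facility = character(),
        ward = character(), medical_service = character(),
        status = character(), ambiguity_flag = logical()
      )
    }
    copy(tmpl)
  }
})

empty_observations <- local({
  tmpl <- NULL
  function() {
    if (is.null(tmpl)) {
      tmpl <<- data.table(
        episode_id = character(), encounter_id = character(),
        category = character(),
        obs_time = as.POSIXct(character(), tz = "UTC"),
        event_key = character(), result_name = character()
      )
    }
    copy(tmpl)
  }
})

empty_orphans <- local({
  tmpl <- NULL
  function() {
    if (is.null(tmpl)) {
      tmpl <<- cbind(classified_template(),
                     data.table(orphan_reason = character()))
    }
    copy(tmpl)
  }
})

#' Choose the Initiate record a Complete closes
#'
#' Candidates must belong to the same encounter, start at or before the
#' Complete, and not already be closed (a Complete can never close an
#' Initiate that lies in its future). Among candidates the latest Initiate
#' wins; exact ties break to the lexicographically smallest event key.
#'
#' @param open_initiates `data.table` of candidate Initiate records
#'   (same encounter, still open).
#' @param complete a one-row `data.table`, the Complete record.
#' @param policy a [window_policy()]; with `match_product_type = TRUE`
#'   candidates are further restricted to the Complete's product value.
#' @return the row index into `open_initiates` of the chosen candidate, or
#'   `0L` when none qualifies; the number of qualifying candidates is
#'   attached as attribute `"n_candidates"`.
#' @export
match_complete <- function(open_initiates, complete, policy = window_policy()) {
  match_complete_vec(as.numeric(open_initiates$event_dt_tm),
                     open_initiates$event_key,
                     open_initiates$result_value,
                     as.numeric(complete$event_dt_tm),
                     complete$result_value, policy)
}

# the matching rule on bare vectors (shared by the batch reconstruction)
match_complete_vec <- function(init_time, init_key, init_val,
                               complete_time, complete_val, policy) {
  if (!length(init_time)) {
    return(structure(0L, n_candidates = 0L))
  }
  ok <- init_time <= complete_time
  if (isTRUE(policy$match_product_type) && !is.na(complete_val)) {
    ok <- ok & !is.na(init_val) & init_val == complete_val
  }
  cand <- which(ok)
  if (!length(cand)) {
    return(structure(0L, n_candidates = 0L))
  }
  tmax <- max(init_time[cand])
  at_max <- cand[init_time[cand] == tmax]
  chosen <- at_max[order(init_key[at_max])][1L]
  structure(chosen, n_candidates = length(cand))
}

# reconstruct all episodes of one encounter from its active events;
# works on bare column vectors - this runs once per touched encounter per
# batch, so it must stay cheap
reconstruct_encounter <- function(ev, policy) {
  ord <- order(ev$event_dt_tm, ev$event_key)
  ev <- ev[ord]
  role <- ev$role
  key <- ev$event_key
  tnum <- as.numeric(ev$event_dt_tm)

  init <- which(role == "INITIATE")
  orphan_idx <- integer()
  orphan_reason <- character()
  add_orphans <- function(idx, reason) {
    orphan_idx <<- c(orphan_idx, idx)
    orphan_reason <<- c(orphan_reason, rep(reason, length(idx)))
  }
  add_orphans(which(role == "OTHER"), "unclassified-result-name")

  if (!length(init)) {
    add_orphans(which(role %chin% c("COMPLETE", "CONSENT", "COMPATIBILITY",
                                    "OBSERVATION")),
                "no-initiate-in-encounter")
    orphans <- cbind(ev[orphan_idx],
                     data.table(orphan_reason = orphan_reason))
    return(list(episodes = empty_episodes(),
                observations = empty_observations(), orphans = orphans))
  }

  completes <- which(role == "COMPLETE")
  n_init <- length(init)
  matched_complete_key <- rep(NA_character_, n_init)
  matched_end_num <- rep(NA_real_, n_init)
  ambiguity <- rep(FALSE, n_init)
  open <- rep(TRUE, n_init)
  init_val <- ev$result_value[init]

  for (ci in completes) {
    cand_idx <- which(open)
    pick <- match_complete_vec(tnum[init[cand_idx]], key[init[cand_idx]],
                               init_val[cand_idx], tnum[ci],
                               ev$result_value[ci], policy)
    if (pick == 0L) {
      add_orphans(ci, "unmatched-complete")
      next
    }
    j <- cand_idx[pick]
    open[j] <- FALSE
    matched_complete_key[j] <- key[ci]
    matched_end_num[j] <- tnum[ci]
    ambiguity[j] <- attr(pick, "n_candidates") > 1L
  }

  start_num <- tnum[init]
  closed <- !is.na(matched_complete_key)
  horizon <- ifelse(closed,
                    matched_end_num + .mins(policy$post_window_min),
                    start_num + .mins(60L * policy$hourly_max_subintervals +
                                        policy$post_window_min))

  obs <- which(role == "OBSERVATION")
  consents <- which(role == "CONSENT")
  compats <- which(role == "COMPATIBILITY")

  pick_support <- function(pool, lo, hi) {
    # latest record inside [lo, hi]; ties to the smallest event key
    sel <- pool[tnum[pool] >= lo & tnum[pool] <= hi]
    if (!length(sel)) return(NA_character_)
    at <- sel[tnum[sel] == max(tnum[sel])]
    sort(key[at])[1L]
  }

  consent_key <- character(n_init)
  compat_key <- character(n_init)
  obs_ep <- vector("list", n_init)
  obs_used <- rep(FALSE, length(obs))
  consent_used <- rep(FALSE, length(consents))
  compat_used <- rep(FALSE, length(compats))

  for (j in seq_len(n_init)) {
    lo <- start_num[j] - .mins(policy$consent_lookback_min)
    hi <- start_num[j] + .mins(policy$baseline_after_min)
    consent_key[j] <- pick_support(consents, lo, hi)
    compat_key[j] <- pick_support(compats, lo, hi)
    consent_used <- consent_used |
      (tnum[consents] >= lo & tnum[consents] <= hi)
    compat_used <- compat_used | (tnum[compats] >= lo & tnum[compats] <= hi)

    in_win <- tnum[obs] >= start_num[j] - .mins(policy$baseline_before_min) &
      tnum[obs] <= horizon[j]
    obs_used <- obs_used | in_win
    obs_ep[[j]] <- obs[in_win]
  }

  n_per_ep <- lengths(obs_ep)
  obs_flat <- unlist(obs_ep)
  observations <- if (length(obs_flat)) {
    data.table(
      episode_id = rep(paste0("EP-", key[init]), n_per_ep),
      encounter_id = ev$encounter_id[obs_flat],
      category = ev$category[obs_flat],
      obs_time = ev$event_dt_tm[obs_flat],
      event_key = key[obs_flat],
      result_name = ev$result_name[obs_flat])
  } else {
    empty_observations()
  }

  episodes <- data.table(
    episode_id = paste0("EP-", key[init]),
    encounter_id = ev$encounter_id[init],
    patient_id = ev$patient_id[init],
    initiate_key = key[init],
    complete_key = matched_complete_key,
    start_time = ev$event_dt_tm[init],
    end_time = .POSIXct(matched_end_num, tz = "UTC"),
    consent_key = consent_key,
    compatibility_key = compat_key,
    product_type = init_val,
    facility = ev$facility[init],
    ward = ev$ward[init],
    medical_service = ev$medical_service[init],
    status = ifelse(closed, "CLOSED", "OPEN"),
    ambiguity_flag = ambiguity
  )

  add_orphans(obs[!obs_used], "unattached-observation")
  add_orphans(consents[!consent_used], "unattached-consent")
  add_orphans(compats[!compat_used], "unattached-compatibility")
  orphans <- if (length(orphan_idx)) {
    cbind(ev[orphan_idx], data.table(orphan_reason = orphan_reason))
  } else {
    empty_orphans()
  }

  list(episodes = episodes, observations = observations, orphans = orphans)
}

#' Rebuild transfusion episodes from the active event set
#'
#' One episode per active Initiate record, always. Completes are matched
#' by [match_complete()]; consent, compatibility and vital-sign
#' observations are attributed per [attach_observations()] windows.
#' Observations are shared at encounter level: one reading may attach to
#' several concurrent episodes, since vitals are measured on the patient,
#' not the blood product. Records that cannot be tied to any episode
#' become orphans — reported, never dropped. Output is deterministic for
#' a given active set.
#'
#' @param active classified active records (an `event_store`'s `active`
#'   table, or any table of the same shape).
#' @param policy a [window_policy()].
#' @return an object of class `reconstruction`: list of `episodes`,
#'   `observations` (long attribution table) and `orphans`.
#' @export
build_episodes <- function(active, policy = window_policy()) {
  active <- as.data.table(active)
  if (nrow(active) == 0L) {
    return(new_reconstruction(empty_episodes(), empty_observations(),
                              empty_orphans()))
  }
  parts <- split(active, by = "encounter_id", sorted = TRUE)
  res <- lapply(parts, reconstruct_encounter, policy = policy)
  new_reconstruction(
    rbindlist(c(list(empty_episodes()), lapply(res, `[[`, "episodes"))),
    rbindlist(c(list(empty_observations()), lapply(res, `[[`, "observations"))),
    rbindlist(c(list(empty_orphans()), lapply(res, `[[`, "orphans")))
  )
}

new_reconstruction <- function(episodes, observations, orphans) {
  setorderv(episodes, c("start_time", "episode_id"))
  setorderv(observations, c("episode_id", "obs_time", "event_key"))
  setorderv(orphans, c("event_dt_tm", "event_key"))
  structure(list(episodes = episodes[], observations = observations[],
                 orphans = orphans[]),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("<reconstruction> %d episodes (%d closed), %d attributed observations, %d orphans\n",
              nrow(x$episodes), sum(x$episodes$status == "CLOSED"),
              nrow(x$observations), nrow(x$orphans)))
  invisible(x)
}

#' Attach supporting records to one episode
#'
#' Attribution windows: every observation of the encounter whose
#' timestamp lies in `[start - baseline_before, horizon]` attaches, where
#' the horizon is `end + post_window` for closed episodes and
#' `start + 60 * hourly_max + post_window` for open ones; a consent
#' (respectively compatibility) record attaches if one exists in
#' `[start - consent_lookback, start + baseline_after]`. All bounds are
#' closed.
#'
#' @param episode one-row episode table (see [build_episodes()]).
#' @param encounter_events active classified records of the same
#'   encounter.
#' @param policy a [window_policy()].
#' @return list with the updated one-row `episode` (consent/compatibility
#'   keys filled) and its `observations` attribution table.
#' @export
attach_observations <- function(episode, encounter_events,
                                policy = window_policy()) {
  ev <- as.data.table(encounter_events)
  stopifnot(nrow(episode) == 1L)
  start <- episode$start_time
  closed <- identical(episode$status, "CLOSED") && !is.na(episode$end_time)
  horizon <- if (closed) {
    episode$end_time + .mins(policy$post_window_min)
  } else {
    start + .mins(60L * policy$hourly_max_subintervals + policy$post_window_min)
  }
  obs <- ev[role == "OBSERVATION" &
              event_dt_tm >= start - .mins(policy$baseline_before_min) &
              event_dt_tm <= horizon]
  observations <- if (nrow(obs)) {
    data.table(episode_id = episode$episode_id,
               encounter_id = obs$encounter_id, category = obs$category,
               obs_time = obs$event_dt_tm, event_key = obs$event_key,
               result_name = obs$result_name)
  } else {
    empty_observations()
  }
  lo <- start - .mins(policy$consent_lookback_min)
  hi <- start + .mins(policy$baseline_after_min)
  pick <- function(pool) {
    sel <- pool[event_dt_tm >= lo & event_dt_tm <= hi]
    if (nrow(sel) == 0L) return(NA_character_)
    sel <- sel[event_dt_tm == max(event_dt_tm)]
    sort(sel$event_key)[1L]
  }
  episode <- copy(as.data.table(episode))
  episode[, consent_key := pick(ev[role == "CONSENT"])]
  episode[, compatibility_key := pick(ev[role == "COMPATIBILITY"])]
  setorderv(observations, c("episode_id", "obs_time", "event_key"))
  list(episode = episode[], observations = observations[])
}

#' Incrementally update a reconstruction after an upsert
#'
#' Reconstruction is encounter-local, so only the encounters named in the
#' changeset are rebuilt from the active set; untouched encounters keep
#' their previous episodes. The result is identical to a full
#' [build_episodes()] over the active set — incremental processing is an
#' optimization, never a semantic change.
#'
#' @param previous the previous `reconstruction`.
#' @param changeset changeset as returned by [upsert()].
#' @param active the current active set (an `event_store` or its `active`
#'   table).
#' @param policy a [window_policy()].
#' @return an updated `reconstruction`.
#' @export
apply_changeset <- function(previous, changeset, active,
                            policy = window_policy()) {
  if (inherits(active, "event_store")) active <- active$active
  active <- as.data.table(active)
  touched <- unique(changeset$encounter_id)
  if (length(touched) == 0L) return(previous)

  keep_ep <- previous$episodes[!encounter_id %chin% touched]
  keep_obs <- previous$observations[!encounter_id %chin% touched]
  keep_orp <- previous$orphans[!encounter_id %chin% touched]

  sub <- active[encounter_id %chin% touched]
  rebuilt <- build_episodes(sub, policy)

  new_reconstruction(rbind(keep_ep, rebuilt$episodes),
                     rbind(keep_obs, rebuilt$observations),
                     rbind(keep_orp, rebuilt$orphans))
}
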