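# The active-event store.
#
# The EMR never updates a record in place: a correction inserts a fresh
# physical row carrying the same logical event key with a higher UPDT_CNT
# version. The store keeps, per event key, only the highest version seen
# (the active record), logs every replaced record to an append-only
# superseded log, and logs stale redeliveries. Downstream computation only
# ever sees active records. In the source system this is a database
# trigger firing on unique-key violation; here it is an explicit upsert
# with the same behavioral contract, so batches may arrive in any order
# and the store converges to the same active set.

# payload columns compared when two rows claim the same (event_key, updt_cnt)
.payload_cols <- c("patient_id", "encounter_id", "result_name",
                   "result_value", "event_dt_tm", "facility", "ward",
                   "medical_service")

#' Create an empty event store
#'
#' @return an object of class `event_store` with empty `active`,
#'   `superseded` and `stale` tables and a zero ingested-row counter.
#' @export
event_store <- function() {
  tmpl <- classified_template()
  structure(
    list(
      active = copy(tmpl),
      superseded = cbind(copy(tmpl), data.table(reason = character())),
      stale = cbind(copy(tmpl), data.table(reason = character())),
      n_ingested = 0L
    ),
    class = "event_store"
  )
}

classified_template <- local({
  tmpl <- NULL
  function() {
    if (is.null(tmpl)) {
      tmpl <<- cbind(empty_records(),
                     data.table(role = character(), category = character()))
    }
    copy(tmpl)
  }
})

#' @export
print.event_store <- function(x, ...) {
  cat(sprintf("<event_store> %d active / %d superseded / %d stale (%d rows ingested)\n",
              nrow(x$active), nrow(x$superseded), nrow(x$stale), x$n_ingested))
  invisible(x)
}

#' Collapse a batch to one record per event key
#'
#' Within one extract batch only the latest version of each logical event
#' is kept; earlier versions are filtered out before loading. Byte-for-byte
#' duplicate deliveries collapse to one row. Two rows claiming the same
#' `(event_key, updt_cnt)` with different payloads are a hard error — the
#' version counter is the only arbiter of recency, so conflicting payloads
#' at one version are unresolvable.
#'
#' Rows removed by the collapse are returned in the `"superseded"`
#' attribute (older versions) and the `"duplicates"` attribute (identical
#' redeliveries), so callers can keep the row-conservation ledger exact.
#'
#' @param records classified canonical records of one batch.
#' @return the surviving records, original order preserved, with
#'   attributes `superseded` and `duplicates`.
#' @export
dedupe_within_batch <- function(records) {
  records <- as.data.table(records)
  if (nrow(records) == 0L) {
    out <- copy(records)
    setattr(out, "superseded", copy(records))
    setattr(out, "duplicates", copy(records))
    return(out)
  }
  rec <- copy(records)[, .ord := .I]
  # identical redeliveries: same key, same version, same payload
  dup <- duplicated(rec, by = c("event_key", "updt_cnt", .payload_cols))
  duplicates <- rec[dup]
  rec <- rec[!dup]
  # conflicting payloads at one version are unresolvable
  conflict <- rec[, list(n = .N), by = c("event_key", "updt_cnt")]
  conflict <- conflict[conflict$n > 1L]
  if (nrow(conflict)) {
    stop("version conflict: event key(s) ",
         paste(unique(conflict$event_key), collapse = ", "),
         " carry the same UPDT_CNT with different payloads", call. = FALSE)
  }
  rec[, is_max := updt_cnt == max(updt_cnt), by = event_key]
  older <- rec[!(is_max)]
  kept <- rec[(is_max)]
  setorderv(kept, ".ord")
  setorderv(older, ".ord")
  kept[, c("is_max", ".ord") := NULL]
  older[, c("is_max", ".ord") := NULL]
  duplicates[, .ord := NULL]
  setattr(kept, "superseded", older[])
  setattr(kept, "duplicates", duplicates[])
  kept[]
}

#' Upsert a deduplicated batch into the store
#'
#' Implements the invalidation contract: an incoming record with a higher
#' version than the active one replaces it and the replaced record is
#' logged as superseded; an incoming record with a lower version, or an
#' identical redelivery of the active version, is discarded as stale (out
#' of order batches are expected, never an error). An incoming record
#' whose version equals the active one but whose payload differs raises a
#' version-conflict error. The changeset lists every event key whose
#' active record changed, with action `"insert"` or `"replace"`.
#'
#' @param store an `event_store`.
#' @param records classified records, at most one per event key (see
#'   [dedupe_within_batch()]).
#' @return list with the updated `store` and the `changeset` (a
#'   `data.table` of `event_key`, `action`, `encounter_id`).
#' @export
upsert <- function(store, records) {
  stopifnot(inherits(store, "event_store"))
  records <- as.data.table(records)
  if (anyDuplicated(records$event_key)) {
    stop("upsert expects at most one record per event key; run dedupe_within_batch first",
         call. = FALSE)
  }
  store$n_ingested <- store$n_ingested + nrow(records)
  if (nrow(records) == 0L) {
    return(list(store = store, changeset = empty_changeset()))
  }
  cols <- names(classified_template())
  records <- records[, cols, with = FALSE]

  idx <- match(records$event_key, store$active$event_key)
  is_new <- is.na(idx)

  newrec <- records[is_new]
  oldpos <- idx[!is_new]
  incoming <- records[!is_new]
  act_ver <- store$active$updt_cnt[oldpos]

  higher <- incoming$updt_cnt > act_ver
  equal <- incoming$updt_cnt == act_ver

  if (any(equal)) {
    same <- vapply(which(equal), function(i) {
      a <- store$active[oldpos[i]]
      b <- incoming[i]
      all(vapply(.payload_cols, function(cl) {
        av <- a[[cl]]; bv <- b[[cl]]
        (is.na(av) && is.na(bv)) || identical(unname(av) == unname(bv), TRUE)
      }, logical(1L)))
    }, logical(1L))
    if (!all(same)) {
      bad <- incoming$event_key[which(equal)[!same]]
      stop("version conflict: event key(s) ", paste(bad, collapse = ", "),
           " redelivered at the active version with a different payload",
           call. = FALSE)
    }
  }

  replaced_old <- store$active[oldpos[higher]]
  if (nrow(replaced_old)) {
    store$superseded <- rbind(store$superseded,
                              cbind(replaced_old,
                                    data.table(reason = "replaced")))
  }
  stale_rows <- incoming[!higher]
  if (nrow(stale_rows)) {
    store$stale <- rbind(
      store$stale,
      cbind(stale_rows,
            data.table(reason = ifelse(equal[!higher],
                                       "duplicate-delivery",
                                       "stale-version")))
    )
  }

  active <- store$active
  if (any(higher)) {
    keep <- setdiff(seq_len(nrow(active)), oldpos[higher])
    active <- rbind(active[keep], incoming[higher])
  }
  if (nrow(newrec)) active <- rbind(active, newrec)
  setorderv(active, c("event_key"))
  store$active <- active

  changeset <- rbind(
    data.table(event_key = newrec$event_key, action = "insert",
               encounter_id = newrec$encounter_id),
    data.table(event_key = incoming$event_key[higher], action = "replace",
               encounter_id = incoming$encounter_id[higher])
  )
  # a correction may move an event between encounters; surface the old
  # encounter too so incremental reconstruction revisits both
  if (nrow(replaced_old)) {
    moved <- replaced_old$encounter_id != incoming$encounter_id[higher]
    if (any(moved)) {
      changeset <- rbind(changeset,
                         data.table(event_key = replaced_old$event_key[moved],
                                    action = "replace",
                                    encounter_id = replaced_old$encounter_id[moved]))
    }
  }
  setorderv(changeset, c("event_key", "encounter_id"))
  changeset <- unique(changeset)
  list(store = store, changeset = changeset)
}

empty_changeset <- function() {
  data.table(event_key = character(), action = character(),
             encounter_id = character())
}

#' Ingest a batch: dedupe then upsert
#'
#' The composite operation the pipeline runs per batch. Rows dropped by
#' the within-batch collapse are logged to the superseded (older version)
#' or stale (identical duplicate) tables so that at all times
#' `n_ingested == nrow(active) + nrow(superseded) + nrow(stale)`.
#'
#' @param store an `event_store`.
#' @param records classified canonical records of one batch.
#' @return list with updated `store` and `changeset`.
#' @export
ingest_records <- function(store, records) {
  records <- as.data.table(records)
  cols <- names(classified_template())
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop("ingest_records: records lack column(s) ",
         paste(missing_cols, collapse = ", "),
         " (classify them with a column_map first)", call. = FALSE)
  }
  records <- records[, cols, with = FALSE]
  deduped <- dedupe_within_batch(records)
  dropped_old <- attr(deduped, "superseded")
  dropped_dup <- attr(deduped, "duplicates")
  store$n_ingested <- store$n_ingested + nrow(dropped_old) + nrow(dropped_dup)
  if (nrow(dropped_old)) {
    store$superseded <- rbind(store$superseded,
                              cbind(dropped_old,
                                    data.table(reason = "batch-dedupe")))
  }
  if (nrow(dropped_dup)) {
    store$stale <- rbind(store$stale,
                         cbind(dropped_dup,
                               data.table(reason = "batch-duplicate")))
  }
  upsert(store, deduped)
}

#' Query active (non-superseded) records
#'
#' @param store an `event_store`.
#' @param encounter optional encounter id(s) to restrict to.
#' @param roles optional role(s) to restrict to.
#' @param from,to optional closed time bounds on `event_dt_tm`.
#' @return active records matching every given predicate, sorted by
#'   `event_dt_tm` then `event_key`.
#' @export
active_events <- function(store, encounter = NULL, roles = NULL,
                          from = NULL, to = NULL) {
  out <- store$active
  if (!is.null(encounter)) out <- out[encounter_id %chin% encounter]
  if (!is.null(roles)) out <- out[role %chin% roles]
  if (!is.null(from)) out <- out[event_dt_tm >= from]
  if (!is.null(to)) out <- out[event_dt_tm <= to]
  setorderv(copy(out), c("event_dt_tm", "event_key"))[]
}
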