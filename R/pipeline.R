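# The incremental warehouse pipeline.
#
# A `cdw` object bundles the whole warehouse state: the versioned event
# store, the current reconstruction, per-episode compliance, the
# TRANSFUSION table and the TRANSFUSION_DAILY_FACT table. Ingesting a
# batch runs read -> classify -> dedupe -> upsert -> incremental
# reconstruction -> incremental compliance -> re-aggregation. Because
# every step is either order-insensitive (the store) or recomputed
# encounter-locally from the active set, the final state is identical
# whatever the batching frequency - ingesting one big extract or hundreds
# of hourly ones converges to the same tables.

#' Create an empty clinical data warehouse
#'
#' @param policy a [window_policy()].
#' @param column_map a [column_map()].
#' @param targets per-measure targets from [measure_targets()].
#' @return an object of class `cdw`.
#' @export
cdw_init <- function(policy = window_policy(),
                     column_map = bloodcdw::column_map(),
                     targets = measure_targets()) {
  recon <- new_reconstruction(empty_episodes(), empty_observations(),
                              empty_orphans())
  compliance <- empty_compliance()
  structure(
    list(
      store = event_store(),
      recon = recon,
      compliance = compliance,
      transfusion = transfusion_table(recon, compliance),
      daily_fact = empty_daily_fact(),
      rejects = data.table(),
      policy = policy,
      column_map = column_map,
      targets = targets,
      n_batches = 0L
    ),
    class = "cdw"
  )
}

#' @export
print.cdw <- function(x, ...) {
  cat(sprintf("<cdw> %d batches ingested; %d active events; %d episodes (%d closed); %d fact rows\n",
              x$n_batches, nrow(x$store$active), nrow(x$transfusion),
              sum(x$transfusion$status == "CLOSED"), nrow(x$daily_fact)))
  invisible(x)
}

#' Ingest one extract batch into the warehouse
#'
#' All-or-nothing: the batch is read and validated in full before any
#' state changes, so an unreadable batch leaves the warehouse untouched.
#' The ingest summary (rows read, rejects, inserts, replacements, stale
#' rows, open/closed episode counts) is attached as attribute
#' `"summary"` of the returned warehouse.
#'
#' @param cdw a `cdw`.
#' @param batch either a path to one extract CSV or an already-canonical
#'   records table.
#' @param batch_id label for the batch; defaults to the file name.
#' @return the updated `cdw`.
#' @export
cdw_ingest <- function(cdw, batch, batch_id = NULL) {
  stopifnot(inherits(cdw, "cdw"))
  if (is.character(batch)) {
    stopifnot(length(batch) == 1L)
    res <- read_extract(batch, cdw$column_map,
                        batch_id = batch_id %||% basename(batch))
    records <- res$records
    rejects <- res$rejects
  } else {
    records <- as.data.table(batch)
    if (!is.null(batch_id)) records[, batch_id := batch_id]
    rejects <- data.table()
  }
  records <- classify_records(records, cdw$column_map)

  up <- ingest_records(cdw$store, records)
  cdw$store <- up$store
  changeset <- up$changeset

  touched <- unique(changeset$encounter_id)
  prev_ids <- cdw$recon$episodes[encounter_id %chin% touched]$episode_id

  cdw$recon <- apply_changeset(cdw$recon, changeset, cdw$store, cdw$policy)

  sub <- new_reconstruction(
    copy(cdw$recon$episodes[encounter_id %chin% touched]),
    copy(cdw$recon$observations[encounter_id %chin% touched]),
    empty_orphans())
  fresh <- evaluate_compliance(sub, cdw$policy)
  comp <- rbind(cdw$compliance[!episode_id %chin% prev_ids], fresh)
  setorderv(comp, "episode_id")
  cdw$compliance <- comp[]

  cdw$transfusion <- transfusion_table(cdw$recon, cdw$compliance)
  cdw$daily_fact <- aggregate_daily(cdw$transfusion)
  if (nrow(rejects)) cdw$rejects <- rbind(cdw$rejects, rejects, fill = TRUE)
  cdw$n_batches <- cdw$n_batches + 1L

  setattr(cdw, "summary", list(
    batch_id = if (nrow(records)) records$batch_id[1L] else batch_id,
    rows_read = nrow(records) + nrow(rejects),
    rejects = nrow(rejects),
    inserts = sum(changeset$action == "insert"),
    replacements = length(unique(changeset$event_key[changeset$action == "replace"])),
    stale = nrow(up$store$stale),
    episodes_open = sum(cdw$transfusion$status == "OPEN"),
    episodes_closed = sum(cdw$transfusion$status == "CLOSED")
  ))
  cdw
}

# ---- persistence: CSV snapshots ------------------------------------------

.cdw_time_cols <- list(
  active = "event_dt_tm", superseded = "event_dt_tm", stale = "event_dt_tm",
  transfusion = c("start_time", "end_time"), observations = "obs_time",
  orphans = "event_dt_tm"
)

#' Persist a warehouse as CSV snapshots
#'
#' Writes one CSV per table (`active`, `superseded`, `stale`,
#' `transfusion`, `daily_fact`, `observations`, `orphans`, `rejects`)
#' plus a `meta.json` holding the policy, targets and column map. The
#' `transfusion.csv` and `daily_fact.csv` snapshots are deterministic:
#' identical warehouse states write byte-identical files.
#'
#' @param cdw a `cdw`.
#' @param dir snapshot directory (created if needed).
#' @return `dir`, invisibly.
#' @export
cdw_write <- function(cdw, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  snap <- function(dt, name) {
    out <- copy(as.data.table(dt))
    for (cl in .cdw_time_cols[[name]] %||% character()) {
      if (cl %in% names(out)) out[, (cl) := format_event_time(out[[cl]])]
    }
    if ("date" %in% names(out)) out[, date := format(date, "%Y-%m-%d")]
    fwrite(out, file.path(dir, paste0(name, ".csv")), quote = TRUE, na = "")
  }
  snap(cdw$store$active, "active")
  snap(cdw$store$superseded, "superseded")
  snap(cdw$store$stale, "stale")
  snap(cdw$transfusion, "transfusion")
  snap(cdw$daily_fact, "daily_fact")
  snap(cdw$recon$observations, "observations")
  snap(cdw$recon$orphans, "orphans")
  if (ncol(cdw$rejects)) snap(cdw$rejects, "rejects")
  meta <- list(
    policy = unclass(cdw$policy),
    targets = as.list(cdw$targets),
    column_map = list(mapping = as.list(cdw$column_map$mapping),
                      critical = cdw$column_map$critical,
                      vocabulary = cdw$column_map$vocabulary),
    n_ingested = cdw$store$n_ingested,
    n_batches = cdw$n_batches
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(dir)
}

#' Load a warehouse from CSV snapshots
#'
#' Inverse of [cdw_write()]; ingestion can continue from the loaded
#' state.
#'
#' @param dir snapshot directory.
#' @return a `cdw`.
#' @export
cdw_read <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("no warehouse snapshot at ", dir, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pol <- meta$policy
  policy <- window_policy(
    baseline_before_min = pol$baseline_before_min,
    baseline_after_min = pol$baseline_after_min,
    t15_nominal_min = pol$t15_nominal_min,
    t15_grace_min = pol$t15_grace_min,
    hourly_grace_min = pol$hourly_grace_min,
    hourly_max_subintervals = pol$hourly_max_subintervals,
    post_window_min = pol$post_window_min,
    consent_lookback_min = pol$consent_lookback_min,
    open_episode_policy = pol$open_episode_policy,
    match_product_type = pol$match_product_type)
  voc <- as.data.table(meta$column_map$vocabulary)
  voc[is.na(category) | category == "", category := NA_character_]
  cmap <- column_map(mapping = unlist(meta$column_map$mapping),
                     critical = meta$column_map$critical,
                     vocabulary = voc)
  targets <- measure_targets(overrides = unlist(meta$targets))

  load_csv <- function(name, template) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) return(template)
    dt <- fread(path, colClasses = "character", na.strings = c("", "NA"),
                showProgress = FALSE)
    if (nrow(dt) == 0L) return(template)
    for (cl in names(template)) {
      tcl <- class(template[[cl]])[1L]
      if (tcl == "POSIXct") dt[, (cl) := parse_event_time(dt[[cl]])]
      else if (tcl == "Date") dt[, (cl) := as.Date(dt[[cl]])]
      else if (tcl == "integer") dt[, (cl) := as.integer(dt[[cl]])]
      else if (tcl == "numeric") dt[, (cl) := as.numeric(dt[[cl]])]
      else if (tcl == "logical") dt[, (cl) := as.logical(dt[[cl]])]
    }
    dt[]
  }

  tmpl_store <- cbind(classified_template(), data.table(reason = character()))
  store <- event_store()
  store$active <- load_csv("active", classified_template())
  store$superseded <- load_csv("superseded", tmpl_store)
  store$stale <- load_csv("stale", tmpl_store)
  store$n_ingested <- as.integer(meta$n_ingested)

  tmpl_tf <- transfusion_table(
    new_reconstruction(empty_episodes(), empty_observations(), empty_orphans()),
    empty_compliance())
  transfusion <- load_csv("transfusion", tmpl_tf)
  observations <- load_csv("observations", empty_observations())
  orphans <- load_csv("orphans", empty_orphans())

  episodes <- transfusion[, .episode_cols, with = FALSE]
  compliance <- transfusion[, names(empty_compliance()), with = FALSE]
  recon <- new_reconstruction(copy(episodes), observations, orphans)

  cdw <- cdw_init(policy, cmap, targets)
  cdw$store <- store
  cdw$recon <- recon
  cdw$compliance <- compliance
  cdw$transfusion <- transfusion_table(recon, compliance)
  cdw$daily_fact <- aggregate_daily(cdw$transfusion)
  cdw$n_batches <- as.integer(meta$n_batches)
  rejects_path <- file.path(dir, "rejects.csv")
  if (file.exists(rejects_path) && file.size(rejects_path) > 0) {
    rj <- fread(rejects_path, colClasses = "character",
                na.strings = c("", "NA"), showProgress = FALSE)
    cdw$rejects <- rj
  }
  cdw
}
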