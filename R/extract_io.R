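# Reading and writing raw extract files.
#
# An extract is a plain CSV, one row per clinical event, UTF-8, comma
# separated, header required, ISO-8601 minute-precision timestamps.
# Canonical header: ROW_ID, EVENT_KEY, PATIENT_ID, ENCNTR_ID, RESULT_NAME,
# RESULT_VAL, EVENT_DT_TM, UPDT_CNT, FACILITY, WARD, MED_SERVICE.

#' Read and canonicalize one extract file
#'
#' Parses a raw extract CSV into typed canonical clinical-event records.
#' Mirrors the defensive quality filter of the upstream extraction query:
#' rows missing a value in any critical column are routed to `rejects`
#' with reason `"missing-critical"`; rows whose timestamp does not parse
#' get reason `"bad-timestamp"`, and rows whose version counter is not a
#' non-negative integer get reason `"bad-version"`. The relative order of
#' surviving rows is preserved.
#'
#' @param path path to the CSV extract.
#' @param column_map a [column_map()] describing the source columns.
#' @param batch_id batch label stamped on every surviving record; defaults
#'   to the file name.
#' @return list with `records` (canonical typed `data.table`) and
#'   `rejects` (raw rows plus a `reason` column).
#' @export
read_extract <- function(path, column_map = bloodcdw::column_map(),
                         batch_id = basename(path)) {
  if (!file.exists(path)) stop("extract file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    fread(path, colClasses = "character", na.strings = c("", "NA"),
          encoding = "UTF-8", showProgress = FALSE),
    error = function(e) stop("unreadable extract '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  missing_cols <- setdiff(unname(column_map$mapping), names(raw))
  if (length(missing_cols)) {
    stop("extract '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, unname(column_map$mapping), with = FALSE]
  setnames(raw, unname(column_map$mapping), names(column_map$mapping))
  for (cl in names(raw)) {
    # quoted empty fields survive fread's na.strings; normalize them
    blank <- !is.na(raw[[cl]]) & raw[[cl]] == ""
    if (any(blank)) set(raw, which(blank), cl, NA_character_)
  }

  if (nrow(raw) == 0L) {
    return(list(records = empty_records(), rejects = empty_rejects(raw)))
  }

  reason <- rep(NA_character_, nrow(raw))
  crit <- column_map$critical
  miss_crit <- Reduce(`|`, lapply(crit, function(f) is.na(raw[[f]])))
  reason[miss_crit] <- "missing-critical"

  ts <- parse_event_time(raw$event_dt_tm)
  bad_ts <- is.na(ts) & !miss_crit
  reason[bad_ts] <- "bad-timestamp"

  ver <- suppressWarnings(as.integer(raw$updt_cnt))
  frac <- suppressWarnings(as.numeric(raw$updt_cnt))
  bad_ver <- (is.na(ver) | ver < 0L | (!is.na(frac) & frac != ver)) &
    !miss_crit & !bad_ts
  reason[bad_ver] <- "bad-version"

  keep <- is.na(reason)
  rejects <- cbind(raw[!keep], data.table(reason = reason[!keep]))
  records <- raw[keep]
  if (nrow(records)) {
    records[, `:=`(event_dt_tm = ts[keep], updt_cnt = ver[keep],
                   batch_id = batch_id)]
  } else {
    records <- empty_records()
  }
  setcolorder(records, names(empty_records()))
  list(records = records[], rejects = rejects[])
}

#' Write canonical records as an extract file
#'
#' Inverse of [read_extract()]: writes the canonical columns under the
#' source header names of `column_map`, timestamps formatted at minute
#' precision. Reading the file back yields the same canonical records
#' (round trip identity, up to the batch label).
#'
#' @param records canonical records table.
#' @param path output CSV path.
#' @param column_map a [column_map()].
#' @return `path`, invisibly.
#' @export
write_extract <- function(records, path, column_map = bloodcdw::column_map()) {
  out <- as.data.table(records)[, names(column_map$mapping), with = FALSE]
  out <- copy(out)
  out[, event_dt_tm := format_event_time(event_dt_tm)]
  out[, updt_cnt := as.character(updt_cnt)]
  setnames(out, names(column_map$mapping), unname(column_map$mapping))
  fwrite(out, path, quote = TRUE, na = "")
  invisible(path)
}

empty_records <- local({
  tmpl <- NULL
  function() {
    if (is.null(tmpl)) {
      tmpl <<- data.table(
        row_id = character(), event_key = character(),
        patient_id = character(), encounter_id = character(),
        result_name = character(), result_value = character(),
        event_dt_tm = as.POSIXct(character(), tz = "UTC"),
        updt_cnt = integer(), facility = character(), ward = character(),
        medical_service = character(), batch_id = character()
      )
    }
    copy(tmpl)
  }
})

empty_rejects <- function(raw) {
  cbind(raw[0L], data.table(reason = character()))
}
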