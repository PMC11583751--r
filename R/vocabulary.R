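# Controlled vocabulary and column mapping.
#
# The EMR stores every clinical event as one long-format row whose
# RESULT_NAME carries the event type. The same vocabulary drives both the
# synthetic simulator and classification during ingestion, so the two can
# never drift apart.

.roles <- c("INITIATE", "COMPLETE", "CONSENT", "COMPATIBILITY",
            "OBSERVATION", "OTHER")
.categories <- c("PULSE", "RESP_RATE", "TEMPERATURE", "BLOOD_PRESSURE")

.canonical_fields <- c(
  row_id = "ROW_ID", event_key = "EVENT_KEY", patient_id = "PATIENT_ID",
  encounter_id = "ENCNTR_ID", result_name = "RESULT_NAME",
  result_value = "RESULT_VAL", event_dt_tm = "EVENT_DT_TM",
  updt_cnt = "UPDT_CNT", facility = "FACILITY", ward = "WARD",
  medical_service = "MED_SERVICE"
)

.default_critical <- c("event_key", "encounter_id", "result_name",
                       "event_dt_tm", "updt_cnt")

#' Default clinical-event vocabulary
#'
#' Maps each RESULT_NAME string to its role in a transfusion episode and,
#' for vital-sign observations, to one of the four monitored categories.
#' The observation source forms cover the extractable EMR documentation
#' forms: pulse as peripheral pulse rate or heart rate; respiratory rate;
#' temperature as axillary, oesophageal, oral or tympanic; blood pressure
#' as systolic or diastolic. Any record in a category satisfies that
#' category.
#'
#' @return a `data.table` with columns `result_name`, `role`, `category`.
#' @export
default_vocabulary <- function() {
  data.table(
    result_name = c(
      "Transfusion Initiated",
      "Transfusion Completed",
      "Blood Product Consent",
      "Blood Compatibility Check",
      "Peripheral Pulse Rate", "Heart Rate",
      "Respiratory Rate",
      "Temperature Axillary", "Temperature Oesophageal",
      "Temperature Oral", "Temperature Tympanic",
      "Systolic Blood Pressure", "Diastolic Blood Pressure"
    ),
    role = c(
      "INITIATE", "COMPLETE", "CONSENT", "COMPATIBILITY",
      rep("OBSERVATION", 9L)
    ),
    category = c(
      rep(NA_character_, 4L),
      "PULSE", "PULSE",
      "RESP_RATE",
      rep("TEMPERATURE", 4L),
      "BLOOD_PRESSURE", "BLOOD_PRESSURE"
    )
  )
}

#' Column map: source columns, critical columns, vocabulary
#'
#' Describes how a raw extract maps onto the canonical clinical-event
#' record: one source column per canonical field, the set of critical
#' fields a row must populate to survive ingestion, and the RESULT_NAME
#' vocabulary used to classify rows. Porting the pipeline to a different
#' EMR extract is a matter of renaming columns here.
#'
#' @param mapping named character vector, canonical field -> source column
#'   name. Defaults to the canonical extract header.
#' @param critical canonical field names that must be non-missing; rows
#'   failing this are rejected, never silently dropped.
#' @param vocabulary a vocabulary table as from [default_vocabulary()].
#' @return an object of class `column_map`.
#' @export
column_map <- function(mapping = NULL, critical = NULL, vocabulary = NULL) {
  m <- .canonical_fields
  if (!is.null(mapping)) {
    bad <- setdiff(names(mapping), names(.canonical_fields))
    if (length(bad)) {
      stop("unknown canonical field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    m[names(mapping)] <- mapping
  }
  if (anyDuplicated(m)) {
    stop("column_map: each canonical field needs a distinct source column",
         call. = FALSE)
  }
  crit <- if (is.null(critical)) .default_critical else critical
  bad <- setdiff(crit, names(.canonical_fields))
  if (length(bad)) {
    stop("unknown critical field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  voc <- if (is.null(vocabulary)) default_vocabulary() else as.data.table(vocabulary)
  if (!all(c("result_name", "role", "category") %in% names(voc))) {
    stop("vocabulary needs columns result_name, role, category", call. = FALSE)
  }
  if (anyDuplicated(voc$result_name)) {
    stop("vocabulary: each result_name may appear only once (roles and categories must partition the vocabulary)",
         call. = FALSE)
  }
  if (!all(voc$role %in% setdiff(.roles, "OTHER"))) {
    stop("vocabulary roles must be one of ",
         paste(setdiff(.roles, "OTHER"), collapse = ", "), call. = FALSE)
  }
  obs <- voc$role == "OBSERVATION"
  if (any(is.na(voc$category[obs])) || any(!voc$category[obs] %in% .categories)) {
    stop("every OBSERVATION needs a category in ",
         paste(.categories, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(voc$category[!obs]))) {
    stop("only OBSERVATION rows may carry a category", call. = FALSE)
  }
  structure(list(mapping = m, critical = crit, vocabulary = voc),
            class = "column_map")
}

#' @export
print.column_map <- function(x, ...) {
  cat("<column_map>\n  source columns:",
      paste(sprintf("%s<-%s", names(x$mapping), x$mapping), collapse = ", "),
      "\n  critical:", paste(x$critical, collapse = ", "),
      "\n  vocabulary:", nrow(x$vocabulary), "result names\n")
  invisible(x)
}

#' Read a column map from a YAML or JSON config file
#'
#' The file may define `mapping` (canonical field -> source column),
#' `critical` (list of canonical fields) and `vocabulary` (list of
#' `{result_name, role, category}` entries). Omitted parts fall back to
#' the defaults.
#'
#' @param path file path.
#' @return a `column_map`.
#' @export
read_column_map <- function(path) {
  if (!file.exists(path)) stop("column map file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  voc <- NULL
  if (!is.null(cfg$vocabulary)) {
    voc <- rbindlist(lapply(cfg$vocabulary, function(e) {
      data.table(result_name = e$result_name, role = e$role,
                 category = if (is.null(e$category)) NA_character_ else e$category)
    }))
  }
  column_map(mapping = unlist(cfg$mapping), critical = unlist(cfg$critical),
             vocabulary = voc)
}

#' Classify a clinical event by its result name
#'
#' Partitions events by RESULT_NAME into their role (Initiate, Complete,
#' consent, compatibility, observation) and, for observations, the
#' vital-sign category. Total and deterministic: names absent from the
#' vocabulary classify as `OTHER` and are retained downstream, never
#' dropped.
#'
#' @param result_name character vector of RESULT_NAME values.
#' @param column_map a [column_map()].
#' @return list with character vectors `role` and `category` (`NA` unless
#'   the role is `OBSERVATION`).
#' @export
classify <- function(result_name, column_map = bloodcdw::column_map()) {
  voc <- column_map$vocabulary
  idx <- match(result_name, voc$result_name)
  role <- voc$role[idx]
  role[is.na(idx)] <- "OTHER"
  category <- voc$category[idx]
  category[is.na(idx)] <- NA_character_
  list(role = role, category = category)
}

# add role/category columns to a canonical records table (by reference-safe copy)
classify_records <- function(records, column_map) {
  records <- copy(as.data.table(records))
  cl <- classify(records$result_name, column_map)
  records[, `:=`(role = cl$role, category = cl$category)]
  records[]
}
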