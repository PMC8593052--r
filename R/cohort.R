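#' Longitudinal inpatient cohort container
#'
#' A cohort bundles three long-format tables that describe inpatient stays on
#' a common continuous time axis (hours relative to an arbitrary cohort
#' epoch):
#'
#' * `admissions`: one row per stay — `admission_id`, `patient_id`,
#'   `admit_time`, `discharge_time`;
#' * `measurements`: timestamped clinical parameter values — `admission_id`,
#'   `time`, `parameter`, `value`;
#' * `events`: timestamped clinical events — `admission_id`, `time`, `kind`
#'   with `kind` one of `antibiotic_administration`, `culture_sample`,
#'   `ews_assessment`.
#'
#' Validation enforces: unique admission ids, one patient per admission,
#' `discharge_time > admit_time`, measurement parameters restricted to the
#' schema, finite values, event kinds in the closed set, referential
#' integrity of `admission_id`, and all measurement/event times inside their
#' admission interval. Rows are sorted by admission and time on construction.
#' Duplicate measurements of the same (admission, time, parameter) triple are
#' retained; they are merged later by hourly averaging.
#'
#' @param admissions,measurements,events data.frames as described above.
#' @param schema a [parameter_schema]; defaults to the packaged 25-parameter
#'   panel.
#' @return An object of class `cohort`.
#' @seealso [read_cohort()], [write_cohort()], [filter_admissions()]
#' @export
cohort <- function(admissions, measurements = NULL, events = NULL,
                   schema = default_parameter_schema()) {
  assert_schema(schema)
  adm <- as.data.table(admissions)
  mea <- if (is.null(measurements)) {
    data.table(admission_id = character(), time = numeric(),
               parameter = character(), value = numeric())
  } else as.data.table(measurements)
  eve <- if (is.null(events)) {
    data.table(admission_id = character(), time = numeric(), kind = character())
  } else as.data.table(events)

  need_cols(adm, c("admission_id", "patient_id", "admit_time", "discharge_time"),
            "admissions")
  need_cols(mea, c("admission_id", "time", "parameter", "value"), "measurements")
  need_cols(eve, c("admission_id", "time", "kind"), "events")

  adm[, `:=`(admission_id = as.character(admission_id),
             patient_id = as.character(patient_id),
             admit_time = as.numeric(admit_time),
             discharge_time = as.numeric(discharge_time))]
  mea[, `:=`(admission_id = as.character(admission_id),
             time = as.numeric(time),
             parameter = as.character(parameter),
             value = as.numeric(value))]
  eve[, `:=`(admission_id = as.character(admission_id),
             time = as.numeric(time),
             kind = as.character(kind))]

  obj <- structure(
    list(admissions = adm, measurements = mea, events = eve, schema = schema),
    class = "cohort"
  )
  validate_cohort(obj)
  setorder(obj$admissions, admission_id)
  setorder(obj$measurements, admission_id, time, parameter)
  setorder(obj$events, admission_id, time, kind)
  obj
}

event_kinds <- function() {
  c("antibiotic_administration", "culture_sample", "ews_assessment")
}

need_cols <- function(dt, cols, table_name) {
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stop(sprintf("%s table is missing required column(s): %s",
                 table_name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a cohort's invariants
#'
#' @param x a `cohort`.
#' @return `x`, invisibly; errors describe the offending rows or values.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  adm <- x$admissions; mea <- x$measurements; eve <- x$events

  if (anyDuplicated(adm$admission_id)) {
    stop("duplicate admission_id: ",
         paste(unique(adm$admission_id[duplicated(adm$admission_id)]), collapse = ", "))
  }
  bad_int <- adm[!(is.finite(admit_time) & is.finite(discharge_time) &
                     discharge_time > admit_time)]
  if (nrow(bad_int)) {
    stop("discharge_time must exceed admit_time for admission(s): ",
         paste(bad_int$admission_id, collapse = ", "))
  }

  unknown <- setdiff(unique(mea$parameter), x$schema$parameter)
  if (length(unknown)) {
    stop("measurement parameter(s) not in schema: ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(mea) && any(!is.finite(mea$value))) {
    stop("non-finite measurement values for parameter(s): ",
         paste(unique(mea$parameter[!is.finite(mea$value)]), collapse = ", "))
  }
  bad_kind <- setdiff(unique(eve$kind), event_kinds())
  if (length(bad_kind)) {
    stop("unknown event kind(s): ", paste(bad_kind, collapse = ", "))
  }

  dang_m <- setdiff(unique(mea$admission_id), adm$admission_id)
  dang_e <- setdiff(unique(eve$admission_id), adm$admission_id)
  if (length(dang_m) || length(dang_e)) {
    stop("referential-integrity error: admission_id(s) not in admissions table: ",
         paste(unique(c(dang_m, dang_e)), collapse = ", "))
  }

  ## times must lie inside their admission interval
  bounds <- adm[, .(admission_id, admit_time, discharge_time)]
  mck <- bounds[mea, on = "admission_id"]
  out_m <- mck[time < admit_time | time > discharge_time]
  if (nrow(out_m)) {
    stop("measurement time outside admission interval for admission(s): ",
         paste(unique(out_m$admission_id), collapse = ", "))
  }
  eck <- bounds[eve, on = "admission_id"]
  out_e <- eck[time < admit_time | time > discharge_time]
  if (nrow(out_e)) {
    stop("event time outside admission interval for admission(s): ",
         paste(unique(out_e$admission_id), collapse = ", "))
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d admissions, %d patients, %d measurements, %d events\n",
              nrow(x$admissions), length(unique(x$admissions$patient_id)),
              nrow(x$measurements), nrow(x$events)))
  invisible(x)
}

#' Read a cohort from its three delimited tables
#'
#' Comma-separated UTF-8 text with a header row. Expected columns:
#' `admissions.csv`: `admission_id,patient_id,admit_time,discharge_time`;
#' `measurements.csv`: `admission_id,time,parameter,value`;
#' `events.csv`: `admission_id,time,kind`. Times are numeric hours.
#'
#' @param admissions_path,measurements_path,events_path file paths.
#' @inheritParams cohort
#' @return a validated `cohort`.
#' @export
read_cohort <- function(admissions_path, measurements_path, events_path,
                        schema = default_parameter_schema()) {
  for (p in c(admissions_path, measurements_path, events_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  adm <- fread(admissions_path, colClasses = list(character = "admission_id"))
  mea <- fread(measurements_path, colClasses = list(character = "admission_id"))
  eve <- fread(events_path, colClasses = list(character = "admission_id"))
  cohort(adm, mea, eve, schema = schema)
}

#' Write a cohort to a directory as three CSV files
#'
#' The inverse of [read_cohort()]: `read_cohort()` on the written files
#' reproduces the cohort up to row order.
#'
#' @param x a `cohort`.
#' @param directory output directory, created if absent.
#' @return named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(x, directory) {
  stopifnot(inherits(x, "cohort"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) stop("cannot create directory: ", directory)
  }
  paths <- c(
    admissions = file.path(directory, "admissions.csv"),
    measurements = file.path(directory, "measurements.csv"),
    events = file.path(directory, "events.csv")
  )
  tryCatch({
    fwrite(x$admissions, paths[["admissions"]])
    fwrite(x$measurements, paths[["measurements"]])
    fwrite(x$events, paths[["events"]])
  }, error = function(e) {
    stop("failed writing cohort under ", directory, ": ", conditionMessage(e))
  })
  invisible(paths)
}

#' Length-of-stay inclusion filter
#'
#' Retains admissions whose length of stay lies in
#' `[min_los_hours, max_los_days * 24]` (both bounds inclusive: stays
#' *shorter than* 24 h or *longer than* 50 days are excluded).
#' Measurements and events of dropped admissions are removed with them.
#'
#' @param x a `cohort`.
#' @param min_los_hours minimum stay, hours (default 24).
#' @param max_los_days maximum stay, days (default 50).
#' @return the filtered `cohort`, with attribute `"dropped"` holding the
#'   number of excluded admissions (also reported via `message()`).
#' @export
filter_admissions <- function(x, min_los_hours = 24, max_los_days = 50) {
  stopifnot(inherits(x, "cohort"), min_los_hours >= 0, max_los_days > 0)
  los <- x$admissions$discharge_time - x$admissions$admit_time
  keep <- los >= min_los_hours & los <= max_los_days * 24
  kept_ids <- x$admissions$admission_id[keep]
  out <- structure(
    list(
      admissions = x$admissions[keep],
      measurements = x$measurements[admission_id %chin% kept_ids],
      events = x$events[admission_id %chin% kept_ids],
      schema = x$schema
    ),
    class = "cohort"
  )
  dropped <- sum(!keep)
  message(sprintf("filter_admissions: dropped %d of %d admissions (length-of-stay outside [%g h, %g d])",
                  dropped, length(keep), min_los_hours, max_los_days))
  attr(out, "dropped") <- dropped
  out
}
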