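#' SOFA score series on an hourly grid
#'
#' A `sofa_series` is a step-function representation of the Sequential Organ
#' Failure Assessment (SOFA) total score across one admission, evaluated on
#' an hourly grid `admit_time + 0, 1, ..., floor(length of stay)`. Scores are
#' integers in 0--24.
#'
#' [sofa_from_table()] builds the series from precomputed (time, score)
#' pairs by forward-filling onto the grid (grid points before the first
#' recorded score carry that first score). [compute_sofa_series()] scores raw
#' measurements against a configurable per-organ component table
#' ([sofa_component_table()]); organ systems whose input parameters are
#' entirely absent contribute 0 points (missing-as-normal), which suits
#' general-ward data lacking e.g. Glasgow Coma Scale and vasopressor
#' records.
#'
#' @param times numeric hours, strictly ascending.
#' @param scores integer SOFA totals in `[0, 24]`, one per time.
#' @param admit_time,discharge_time admission interval bounds (hours).
#' @param admission_id optional identifier carried on the result.
#' @return a `sofa_series`: list with `admission_id`, `times` (hourly grid)
#'   and `scores`.
#' @examples
#' s <- sofa_from_table(c(0, 10), c(0, 2), admit_time = 0, discharge_time = 12)
#' s$scores  # 0 for hours 0..9, 2 for hours 10..12
#' @export
sofa_from_table <- function(times, scores, admit_time, discharge_time,
                            admission_id = NA_character_) {
  stopifnot(length(times) == length(scores), length(times) >= 1,
            discharge_time > admit_time)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("SOFA times must be strictly ascending")
  }
  if (any(scores < 0 | scores > 24 | scores != floor(scores))) {
    stop("SOFA scores must be integers in [0, 24]")
  }
  grid <- sofa_grid(admit_time, discharge_time)
  idx <- findInterval(grid, times)           # 0 before first recorded score
  filled <- scores[pmax(idx, 1L)]            # backfill leading points
  new_sofa_series(admission_id, grid, as.integer(filled))
}

sofa_grid <- function(admit_time, discharge_time) {
  admit_time + 0:floor(discharge_time - admit_time)
}

new_sofa_series <- function(admission_id, times, scores) {
  structure(list(admission_id = admission_id, times = times,
                 scores = as.integer(scores)),
            class = "sofa_series")
}

#' @export
print.sofa_series <- function(x, ...) {
  cat(sprintf("<sofa_series> admission %s, %d hourly points, score range %d-%d\n",
              x$admission_id, length(x$times), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Default SOFA component scoring table
#'
#' Threshold rules mapping clinical parameters to per-organ SOFA points,
#' restricted to the organ systems observable from the packaged general-ward
#' schema: coagulation (platelets), liver (bilirubin), renal (creatinine),
#' cardiovascular (mean arterial pressure, derived as `(SBP + 2 DBP)/3` from
#' the two blood-pressure vitals), and respiration (arterial pO2, with
#' thresholds expressed on the raw kPa value assuming ambient-air
#' inspiration). Central nervous system and vasopressor-dependent
#' cardiovascular points are not representable from this schema and are
#' scored 0. A component's score is the highest-points rule its current
#' value satisfies.
#'
#' @return data.table with columns `component`, `parameter`, `op`
#'   (`"lt"` or `"ge"`), `threshold`, `points`.
#' @export
sofa_component_table <- function() {
  rbindlist(list(
    data.table(component = "coagulation", parameter = "B-Platelets", op = "lt",
               threshold = c(150, 100, 50, 20), points = 1:4),
    data.table(component = "liver", parameter = "P-Bilirubin", op = "ge",
               threshold = c(20, 33, 102, 205), points = 1:4),
    data.table(component = "renal", parameter = "P-Creatinine", op = "ge",
               threshold = c(110, 171, 300, 440), points = 1:4),
    data.table(component = "cardiovascular", parameter = "MAP", op = "lt",
               threshold = 70, points = 1L),
    ## PaO2/FiO2 breakpoints 400/300/200/100 mmHg at FiO2 0.21, as raw kPa
    data.table(component = "respiration", parameter = "P(aB)-pO2", op = "lt",
               threshold = c(11.2, 8.4, 5.6, 2.8), points = 1:4)
  ))
}

#' @rdname sofa_from_table
#' @param measurements long table (`admission_id`, `time`, `parameter`,
#'   `value`) for a single admission.
#' @param component_table scoring rules as from [sofa_component_table()];
#'   parameters must belong to the schema (plus the derived `"MAP"`).
#' @param schema the cohort's [parameter_schema].
#' @export
compute_sofa_series <- function(measurements, admit_time, discharge_time,
                                component_table = sofa_component_table(),
                                schema = default_parameter_schema(),
                                admission_id = NA_character_) {
  mea <- as.data.table(measurements)
  need_cols(component_table, c("component", "parameter", "op", "threshold", "points"),
            "component_table")
  known <- c(schema$parameter, "MAP")
  bad <- setdiff(unique(component_table$parameter), known)
  if (length(bad)) {
    stop("component table references unknown parameter(s): ",
         paste(bad, collapse = ", "))
  }
  grid <- sofa_grid(admit_time, discharge_time)

  ## forward-filled most recent value per parameter on the grid
  ffill_on_grid <- function(p) {
    rows <- mea[parameter == p][order(time)]
    if (!nrow(rows)) return(rep(NA_real_, length(grid)))
    idx <- findInterval(grid, rows$time)
    ifelse(idx >= 1, rows$value[pmax(idx, 1L)], NA_real_)
  }
  pars <- setdiff(unique(component_table$parameter), "MAP")
  values <- lapply(pars, ffill_on_grid)
  names(values) <- pars
  if ("MAP" %in% component_table$parameter) {
    sbp <- ffill_on_grid("Systolic blood pressure")
    dbp <- ffill_on_grid("Diastolic blood pressure")
    values[["MAP"]] <- (sbp + 2 * dbp) / 3
  }

  total <- integer(length(grid))
  for (comp in unique(component_table$component)) {
    rules <- component_table[component == comp]
    v <- values[[rules$parameter[1]]]
    pts <- integer(length(grid))
    for (r in seq_len(nrow(rules))) {
      hit <- if (rules$op[r] == "lt") v < rules$threshold[r] else v >= rules$threshold[r]
      hit[is.na(hit)] <- FALSE                 # missing-as-normal
      pts <- pmax(pts, ifelse(hit, rules$points[r], 0L))
    }
    total <- total + pts
  }
  new_sofa_series(admission_id, grid, pmin(total, 24L))
}
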