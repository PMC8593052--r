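#' Temporal framing configuration
#'
#' A framing structure converts a labeled admission into supervised
#' prediction samples. Windows follow the half-open `(a, b]` convention:
#' the observation window covers `(prediction_time - observation_window,
#' prediction_time]` and a positive label requires the onset to fall in
#' `(prediction_time + lead_window, prediction_time + lead_window +
#' prediction_window]`. Supported structures:
#'
#' * `fixed_time_to_onset` — one sample per admission; positives at
#'   `onset - onset_offset`, negatives at a seeded uniform-random time
#'   during admission.
#' * `sliding_window` — prediction times at
#'   `admit + observation_window + k * window_shift`, `k = 0, 1, ...`, up to
#'   discharge; samples at or after onset are censored.
#' * `sliding_window_dynamic` — the sliding grid restricted to times at or
#'   after the first hourly grid point with SOFA > 0, so its samples are a
#'   subset of the sliding-window samples with identical positives.
#' * `on_clinical_demand` — one sample per EWS assessment event.
#'
#' @param structure one of the four structure names above.
#' @param observation_window hours, default 12.
#' @param prediction_window hours, default 12.
#' @param lead_window hours, default 0.
#' @param window_shift hours between sliding predictions, default 6.
#' @param onset_offset hours before onset for `fixed_time_to_onset`,
#'   default 12.
#' @param seed integer seed for the negative-time draws of
#'   `fixed_time_to_onset` (used by [frame_cohort()]).
#' @return a `framing_config` list.
#' @export
framing_config <- function(structure = c("fixed_time_to_onset", "sliding_window",
                                         "sliding_window_dynamic",
                                         "on_clinical_demand"),
                           observation_window = 12, prediction_window = 12,
                           lead_window = 0, window_shift = 6,
                           onset_offset = 12, seed = 1L) {
  structure <- match.arg(structure)
  stopifnot(observation_window >= 0, prediction_window >= 0, lead_window >= 0,
            onset_offset > 0)
  if (structure %in% c("sliding_window", "sliding_window_dynamic") &&
      window_shift <= 0) {
    stop("window_shift must be > 0 for sliding structures")
  }
  base::structure(
    list(structure = structure, observation_window = observation_window,
         prediction_window = prediction_window, lead_window = lead_window,
         window_shift = window_shift, onset_offset = onset_offset,
         seed = as.integer(seed)),
    class = "framing_config")
}

empty_samples <- function() {
  data.table(sample_id = character(), admission_id = character(),
             prediction_time = numeric(), label = integer(),
             structure = character())
}

make_samples <- function(admission_id, times, labels, structure) {
  if (!length(times)) return(empty_samples())
  data.table(
    sample_id = sprintf("%s_%s_%03d", admission_id, abbreviate_structure(structure),
                        seq_along(times)),
    admission_id = admission_id,
    prediction_time = times,
    label = as.integer(labels),
    structure = structure
  )
}

abbreviate_structure <- function(structure) {
  c(fixed_time_to_onset = "fix", sliding_window = "sw",
    sliding_window_dynamic = "swdi", on_clinical_demand = "ocd")[[structure]]
}

## label by onset membership of (t + lead, t + lead + pw]
onset_label <- function(times, onset, cfg) {
  if (is.na(onset)) return(rep(0L, length(times)))
  lo <- times + cfg$lead_window
  as.integer(onset > lo & onset <= lo + cfg$prediction_window)
}

#' Frame one admission: fixed time to onset
#'
#' Positive admissions yield exactly one positive sample at
#' `onset - onset_offset` (none if that time precedes admission); negative
#' admissions yield one negative sample at a uniform-random time in
#' `(admit, discharge]`, drawn from the current RNG state
#' ([frame_cohort()] seeds it from the config for reproducibility).
#'
#' @param admission one-row admissions table.
#' @param outcome one-row outcome table (`onset_time` `NA` when negative).
#' @param cfg a [framing_config()] with matching `structure`.
#' @return samples data.table (`sample_id`, `admission_id`,
#'   `prediction_time`, `label`, `structure`).
#' @export
frame_fixed_time_to_onset <- function(admission, outcome, cfg) {
  stopifnot(cfg$structure == "fixed_time_to_onset")
  adm <- as.data.table(admission); out <- as.data.table(outcome)
  onset <- out$onset_time[1]
  if (!is.na(onset)) {
    t <- onset - cfg$onset_offset
    if (t < adm$admit_time) return(empty_samples())
    make_samples(adm$admission_id, t, 1L, cfg$structure)
  } else {
    t <- adm$admit_time + runif(1) * (adm$discharge_time - adm$admit_time)
    make_samples(adm$admission_id, t, 0L, cfg$structure)
  }
}

sliding_times <- function(admit_time, discharge_time, cfg) {
  first <- admit_time + cfg$observation_window
  if (first > discharge_time) return(numeric())
  seq(first, discharge_time, by = cfg$window_shift)
}

#' Frame one admission: sliding window
#'
#' @inheritParams frame_fixed_time_to_onset
#' @export
frame_sliding_window <- function(admission, outcome, cfg) {
  stopifnot(cfg$structure %in% c("sliding_window", "sliding_window_dynamic"))
  adm <- as.data.table(admission); out <- as.data.table(outcome)
  onset <- out$onset_time[1]
  times <- sliding_times(adm$admit_time, adm$discharge_time, cfg)
  if (!is.na(onset)) times <- times[times < onset]   # post-onset censoring
  make_samples(adm$admission_id, times, onset_label(times, onset, cfg),
               cfg$structure)
}

#' Frame one admission: sliding window with dynamic inclusion
#'
#' Identical to [frame_sliding_window()] except sampling only starts once
#' the admission's SOFA score first exceeds 0: the retained prediction
#' times are the sliding-grid times at or after that first SOFA > 0 grid
#' point. Admissions whose SOFA never exceeds 0 yield no samples.
#'
#' @inheritParams frame_fixed_time_to_onset
#' @param sofa the admission's [sofa_from_table()] series.
#' @export
frame_sliding_dynamic <- function(admission, outcome, sofa, cfg) {
  stopifnot(cfg$structure == "sliding_window_dynamic",
            inherits(sofa, "sofa_series"))
  pos <- which(sofa$scores > 0)
  if (!length(pos)) return(empty_samples())
  incl <- sofa$times[pos[1]]
  base <- frame_sliding_window(admission, outcome, cfg)
  base[prediction_time >= incl]
}

#' Frame one admission: on clinical demand
#'
#' One sample per EWS assessment event, at the event's time; labeling and
#' post-onset censoring as in the sliding structures. The sample interval is
#' whatever the (physician-driven) assessment schedule was.
#'
#' @inheritParams frame_fixed_time_to_onset
#' @param events the admission's event table.
#' @export
frame_on_clinical_demand <- function(admission, outcome, events, cfg) {
  stopifnot(cfg$structure == "on_clinical_demand")
  adm <- as.data.table(admission); out <- as.data.table(outcome)
  eve <- as.data.table(events)
  onset <- out$onset_time[1]
  times <- sort(eve[kind == "ews_assessment", time])
  if (!is.na(onset)) times <- times[times < onset]
  make_samples(adm$admission_id, times, onset_label(times, onset, cfg),
               cfg$structure)
}

#' Frame an entire labeled cohort
#'
#' Applies the configured framing structure to every admission. The
#' negative-time draws of `fixed_time_to_onset` are made under
#' `withr::with_seed(cfg$seed)`, so identical seeds give identical samples.
#'
#' @param x a `cohort`.
#' @param outcomes output of [label_cohort()].
#' @param cfg a [framing_config()].
#' @param sofa long SOFA table (`admission_id`, `time`, `score`); required
#'   for `sliding_window_dynamic`.
#' @return samples data.table; attribute `"class_balance"` holds the
#'   [class_balance()] of the result.
#' @export
frame_cohort <- function(x, outcomes, cfg, sofa = NULL) {
  stopifnot(inherits(x, "cohort"), inherits(cfg, "framing_config"))
  out <- as.data.table(outcomes)
  need_cols(out, c("admission_id", "onset_time"), "outcomes")
  adm <- x$admissions
  out <- out[adm[, .(admission_id)], on = "admission_id"]
  if (cfg$structure == "sliding_window_dynamic") {
    if (is.null(sofa)) stop("sliding_window_dynamic requires a sofa table")
    sof_split <- split(as.data.table(sofa), by = "admission_id")
  }
  if (cfg$structure == "on_clinical_demand") {
    eve_split <- split(x$events, by = "admission_id")
  }

  frame_one <- function(i) {
    a <- adm[i]; o <- out[admission_id == a$admission_id]
    switch(cfg$structure,
      fixed_time_to_onset = frame_fixed_time_to_onset(a, o, cfg),
      sliding_window = frame_sliding_window(a, o, cfg),
      sliding_window_dynamic = {
        srows <- sof_split[[a$admission_id]]
        if (is.null(srows)) return(empty_samples())
        srows <- srows[order(time)]
        series <- sofa_from_table(srows$time, srows$score, a$admit_time,
                                  a$discharge_time, admission_id = a$admission_id)
        frame_sliding_dynamic(a, o, series, cfg)
      },
      on_clinical_demand = {
        ev <- eve_split[[a$admission_id]]
        if (is.null(ev)) ev <- x$events[0]
        frame_on_clinical_demand(a, o, ev, cfg)
      })
  }

  res <- if (cfg$structure == "fixed_time_to_onset") {
    withr::with_seed(cfg$seed, rbindlist(lapply(seq_len(nrow(adm)), frame_one)))
  } else {
    rbindlist(lapply(seq_len(nrow(adm)), frame_one))
  }
  if (!nrow(res)) res <- empty_samples()
  setattr(res, "class_balance", class_balance(res))
  res[]
}

#' Class balance of a sample set
#'
#' @param samples a samples data.table with a `label` column.
#' @return a `class_balance` list: `positives`, `negatives`, `ratio_text`
#'   (`"1:N"` with `N = round(negatives/positives)`; `NA` when there are no
#'   positives).
#' @export
class_balance <- function(samples) {
  s <- as.data.table(samples)
  pos <- sum(s$label == 1L); neg <- sum(s$label == 0L)
  ratio <- if (pos > 0) sprintf("1:%d", round(neg / pos)) else NA_character_
  structure(list(positives = pos, negatives = neg, ratio_text = ratio),
            class = "class_balance")
}

#' @export
print.class_balance <- function(x, ...) {
  cat(sprintf("<class_balance> %d positives, %d negatives (%s)\n",
              x$positives, x$negatives,
              if (is.na(x$ratio_text)) "ratio undefined" else x$ratio_text))
  invisible(x)
}
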