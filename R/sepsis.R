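#' Sepsis-3 labeling configuration
#'
#' Window parameters of the Sepsis-3 operationalization: a suspected
#' infection (SI) is a culture/antibiotic event pair where the antibiotic
#' follows a culture within `max_culture_to_abx` hours, or the culture
#' follows an antibiotic within `max_abx_to_culture` hours; the organ
#' dysfunction criterion is an acute SOFA increase of at least
#' `sofa_delta_threshold` points within the window from
#' `sofa_window_before` hours before to `sofa_window_after` hours after the
#' SI index time (the earlier member of the pair).
#'
#' @param max_culture_to_abx hours, default 72.
#' @param max_abx_to_culture hours, default 24.
#' @param sofa_window_before hours, default 48.
#' @param sofa_window_after hours, default 24.
#' @param sofa_delta_threshold integer points, default 2.
#' @return a `sepsis3_config` list.
#' @export
sepsis3_config <- function(max_culture_to_abx = 72, max_abx_to_culture = 24,
                           sofa_window_before = 48, sofa_window_after = 24,
                           sofa_delta_threshold = 2) {
  stopifnot(max_culture_to_abx > 0, max_abx_to_culture > 0,
            sofa_window_before > 0, sofa_window_after > 0,
            sofa_delta_threshold >= 1)
  structure(list(max_culture_to_abx = max_culture_to_abx,
                 max_abx_to_culture = max_abx_to_culture,
                 sofa_window_before = sofa_window_before,
                 sofa_window_after = sofa_window_after,
                 sofa_delta_threshold = as.integer(sofa_delta_threshold)),
            class = "sepsis3_config")
}

#' Detect suspected-infection events from culture/antibiotic pairs
#'
#' Every qualifying (culture, antibiotic) pair within one admission yields
#' one suspected-infection event with `index_time` equal to the earlier
#' member of the pair. Non-culture, non-antibiotic events (e.g. EWS
#' assessments) are ignored. Overlapping pairs sharing an event are all
#' kept; downstream only the earliest resulting onset matters.
#'
#' @param events event table (`admission_id`, `time`, `kind`) for a single
#'   admission.
#' @param cfg a [sepsis3_config()].
#' @return data.table (`admission_id`, `culture_time`, `abx_time`,
#'   `index_time`), sorted by `index_time`; zero rows when no pair
#'   qualifies.
#' @export
detect_suspected_infection <- function(events, cfg = sepsis3_config()) {
  eve <- as.data.table(events)
  need_cols(eve, c("admission_id", "time", "kind"), "events")
  cul <- eve[kind == "culture_sample", time]
  abx <- eve[kind == "antibiotic_administration", time]
  aid <- if (nrow(eve)) eve$admission_id[1] else NA_character_
  empty <- data.table(admission_id = character(), culture_time = numeric(),
                      abx_time = numeric(), index_time = numeric())
  if (!length(cul) || !length(abx)) return(empty)
  pairs <- CJ(culture_time = cul, abx_time = abx)
  gap <- pairs$abx_time - pairs$culture_time
  keep <- (gap >= 0 & gap <= cfg$max_culture_to_abx) |
    (gap < 0 & -gap <= cfg$max_abx_to_culture)
  pairs <- pairs[keep]
  if (!nrow(pairs)) return(empty)
  pairs[, `:=`(admission_id = aid, index_time = pmin(culture_time, abx_time))]
  setcolorder(pairs, c("admission_id", "culture_time", "abx_time", "index_time"))
  setorder(pairs, index_time, culture_time, abx_time)
  pairs[]
}

#' Assign a Sepsis-3 onset time for one admission
#'
#' For each suspected-infection event, the SOFA series is scanned over the
#' window `[index_time - sofa_window_before, index_time + sofa_window_after]`
#' clipped to the admission. A grid time `t` is an onset candidate when
#' `SOFA(t) - min(SOFA(u) : u in window, u <= t)` reaches the threshold —
#' i.e. an acute increase relative to the running within-window minimum. The
#' reported onset is the earliest candidate over all SI events.
#'
#' @param si_events output of [detect_suspected_infection()].
#' @param sofa a [sofa_from_table()] / [compute_sofa_series()] series.
#' @param cfg a [sepsis3_config()].
#' @return one-row data.table (`admission_id`, `onset_time`,
#'   `si_index_time`), times `NA` when the admission is negative.
#' @export
detect_onset <- function(si_events, sofa, cfg = sepsis3_config()) {
  stopifnot(inherits(sofa, "sofa_series"))
  si <- as.data.table(si_events)
  aid <- if (nrow(si)) si$admission_id[1] else sofa$admission_id
  negative <- data.table(admission_id = aid, onset_time = NA_real_,
                         si_index_time = NA_real_)
  if (!nrow(si)) return(negative)
  best_onset <- Inf; best_index <- NA_real_
  for (i in seq_len(nrow(si))) {
    idx <- si$index_time[i]
    inwin <- sofa$times >= idx - cfg$sofa_window_before &
      sofa$times <= idx + cfg$sofa_window_after
    if (!any(inwin)) next
    s <- sofa$scores[inwin]
    tt <- sofa$times[inwin]
    delta <- s - cummin(s)
    hit <- which(delta >= cfg$sofa_delta_threshold)
    if (length(hit) && tt[hit[1]] < best_onset) {
      best_onset <- tt[hit[1]]
      best_index <- idx
    }
  }
  if (is.finite(best_onset)) {
    data.table(admission_id = aid, onset_time = best_onset,
               si_index_time = best_index)
  } else negative
}

#' Label a whole cohort with Sepsis-3 outcomes
#'
#' Runs suspected-infection detection and onset assignment for every
#' admission. SOFA series are taken from `sofa` (a long table
#' `admission_id,time,score` of precomputed scores) when supplied; otherwise
#' they are computed from the cohort's measurements via
#' [compute_sofa_series()]. Admissions absent from a supplied `sofa` table
#' are treated as constant SOFA 0 with a warning.
#'
#' @param x a filtered `cohort`.
#' @param cfg a [sepsis3_config()].
#' @param sofa optional data.frame (`admission_id`, `time`, `score`).
#' @param component_table per-organ scoring rules, used only when `sofa` is
#'   absent.
#' @return data.table (`admission_id`, `onset_time`, `si_index_time`), one
#'   row per admission, with attribute `"prevalence"` = positives /
#'   admissions.
#' @export
label_cohort <- function(x, cfg = sepsis3_config(), sofa = NULL,
                         component_table = sofa_component_table()) {
  stopifnot(inherits(x, "cohort"))
  adm <- x$admissions
  sof <- if (!is.null(sofa)) as.data.table(sofa) else NULL
  if (!is.null(sof)) need_cols(sof, c("admission_id", "time", "score"), "sofa")
  eve_split <- split(x$events, by = "admission_id")
  sof_split <- if (!is.null(sof)) split(sof, by = "admission_id") else NULL
  mea_split <- if (is.null(sof)) split(x$measurements, by = "admission_id") else NULL

  rows <- vector("list", nrow(adm))
  for (i in seq_len(nrow(adm))) {
    aid <- adm$admission_id[i]
    a0 <- adm$admit_time[i]; a1 <- adm$discharge_time[i]
    series <- if (!is.null(sof)) {
      srows <- sof_split[[aid]]
      if (is.null(srows)) {
        warning("no SOFA series for admission ", aid, "; treating as constant 0")
        sofa_from_table(a0, 0L, a0, a1, admission_id = aid)
      } else {
        srows <- srows[order(time)]
        sofa_from_table(srows$time, srows$score, a0, a1, admission_id = aid)
      }
    } else {
      m <- mea_split[[aid]]
      if (is.null(m)) m <- x$measurements[0]
      compute_sofa_series(m, a0, a1, component_table = component_table,
                          schema = x$schema, admission_id = aid)
    }
    ev <- eve_split[[aid]]
    si <- if (is.null(ev)) x$events[0][, .(admission_id, time, kind)] else ev
    si <- detect_suspected_infection(si, cfg)
    out <- detect_onset(si, series, cfg)
    out$admission_id <- aid
    rows[[i]] <- out
  }
  res <- rbindlist(rows)
  prev <- if (nrow(res)) mean(!is.na(res$onset_time)) else NA_real_
  setattr(res, "prevalence", prev)
  res[]
}
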