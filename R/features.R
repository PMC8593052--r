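#' Extract the raw observation window for one sample
#'
#' Returns the measurements with `time` in `(prediction_time -
#' observation_window, prediction_time]` for the sample's admission. The
#' half-open convention includes a measurement exactly at the prediction
#' time and never anything after it.
#'
#' @param x a `cohort`.
#' @param sample one-row samples table (`admission_id`, `prediction_time`).
#' @param observation_window hours, default 12.
#' @return data.table of windowed measurements.
#' @export
extract_observation <- function(x, sample, observation_window = 12) {
  stopifnot(inherits(x, "cohort"))
  s <- as.data.table(sample)
  tp <- s$prediction_time[1]
  x$measurements[admission_id == s$admission_id[1] &
                   time > tp - observation_window & time <= tp]
}

#' Hourly means within an observation window
#'
#' Collapses multiple values of a parameter within each 1-hour bin to their
#' arithmetic mean. Bins are anchored at the prediction time and counted
#' backwards: bin `h` covers `(prediction_time - h - 1, prediction_time - h]`
#' for `h = 0, 1, ...`.
#'
#' @param raw windowed measurements (from [extract_observation()]).
#' @param prediction_time anchor, hours.
#' @return data.table (`parameter`, `hour_bin`, `value`); empty bins are
#'   simply absent.
#' @export
hourly_mean <- function(raw, prediction_time) {
  m <- as.data.table(raw)
  if (!nrow(m)) {
    return(data.table(parameter = character(), hour_bin = integer(),
                      value = numeric()))
  }
  age <- prediction_time - m$time        # in [0, observation_window)
  m <- m[, .(parameter, hour_bin = as.integer(ceiling(age) - 1L), value)]
  m[hour_bin < 0L, hour_bin := 0L]       # time exactly at prediction time
  m[, .(value = mean(value)), by = .(parameter, hour_bin)]
}

#' Collapse hourly values into two 6-hour timesteps
#'
#' The 12-hour observation window is summarized as two timesteps: `late`
#' averages the available hourly values over the most recent 6 hours
#' (bins 0--5), `early` over the preceding 6 hours (bins 6--11). An
#' all-missing half stays missing.
#'
#' @param hourly output of [hourly_mean()].
#' @param schema a [parameter_schema].
#' @param timestep_hours half-window duration, default 6.
#' @return a `timestep_grid`: list of four named numeric/logical vectors
#'   over the schema parameters — `early`, `late` (values, `NA` = missing)
#'   and `obs_early`, `obs_late` (pre-imputation observability).
#' @export
bin_timesteps <- function(hourly, schema = default_parameter_schema(),
                          timestep_hours = 6) {
  assert_schema(schema)
  h <- as.data.table(hourly)
  pars <- schema$parameter
  early <- late <- setNames(rep(NA_real_, length(pars)), pars)
  if (nrow(h)) {
    agg <- h[, .(value = mean(value)),
             by = .(parameter, timestep = ifelse(hour_bin < timestep_hours,
                                                 "late", "early"))]
    el <- agg[timestep == "early"]; ll <- agg[timestep == "late"]
    early[el$parameter] <- el$value
    late[ll$parameter] <- ll$value
  }
  structure(list(early = early, late = late,
                 obs_early = !is.na(early), obs_late = !is.na(late)),
            class = "timestep_grid")
}

#' Forward/backward imputation across the two timesteps
#'
#' Per parameter: a missing late value is filled from the early one
#' (forward), then a missing early value from the late one (backward); a
#' both-missing parameter stays missing. Idempotent. The pre-imputation
#' observability flags are preserved.
#'
#' @param grid a `timestep_grid`.
#' @return the imputed `timestep_grid`.
#' @export
impute_forward_backward <- function(grid) {
  stopifnot(inherits(grid, "timestep_grid"))
  fill_late <- is.na(grid$late) & !is.na(grid$early)
  grid$late[fill_late] <- grid$early[fill_late]
  fill_early <- is.na(grid$early) & !is.na(grid$late)
  grid$early[fill_early] <- grid$late[fill_early]
  grid
}

#' Assemble the 50-element feature vector
#'
#' Value features are the late (most recent) timestep values; delta
#' features are `late - early`, zero whenever both timesteps originate from
#' a single imputed source. With a 25-parameter schema this yields exactly
#' 50 features. The attached observability masks record pre-imputation
#' availability: a value feature counts as observed when either timestep
#' held data, a delta feature only when both did.
#'
#' @param grid an imputed `timestep_grid`.
#' @param schema the [parameter_schema] the grid was built over.
#' @return named numeric vector of length `2 * nrow(schema)`
#'   (`<id>` then `<id>_delta` per parameter), with attribute `"observed"`
#'   (named logical of the same length).
#' @export
assemble_features <- function(grid, schema = default_parameter_schema()) {
  stopifnot(inherits(grid, "timestep_grid"))
  assert_schema(schema)
  ids <- schema$id
  vals <- unname(grid$late[schema$parameter])
  deltas <- unname(grid$late[schema$parameter] - grid$early[schema$parameter])
  out <- setNames(c(vals, deltas), c(ids, paste0(ids, "_delta")))
  observed <- setNames(
    c(grid$obs_early[schema$parameter] | grid$obs_late[schema$parameter],
      grid$obs_early[schema$parameter] & grid$obs_late[schema$parameter]),
    names(out))
  attr(out, "observed") <- observed
  out
}

#' Build the feature matrix for a set of prediction samples
#'
#' Vectorized pipeline over all samples: windowed extraction, hourly
#' averaging, two-timestep binning, forward/backward imputation and
#' value/delta assembly, as in the per-sample operations. Only data at or
#' before each sample's prediction time can enter its features.
#'
#' @param x a `cohort`.
#' @param samples samples table from [frame_cohort()].
#' @param observation_window hours, default 12.
#' @param timestep_hours hours per timestep, default 6.
#' @return a `feature_set`: list with
#'   * `features`: data.table — `sample_id`, `admission_id`, `structure`,
#'     `label`, then the `2 * nrow(schema)` feature columns (`NA` = missing
#'     after imputation);
#'   * `observed`: data.table of matching logical columns (pre-imputation
#'     observability, value = either timestep, delta = both timesteps);
#'   * `schema`, `observation_window`.
#' @export
featurize_samples <- function(x, samples, observation_window = 12,
                              timestep_hours = 6) {
  stopifnot(inherits(x, "cohort"))
  s <- as.data.table(samples)
  need_cols(s, c("sample_id", "admission_id", "prediction_time", "label"),
            "samples")
  schema <- x$schema
  ids <- schema$id
  feat_names <- c(ids, paste0(ids, "_delta"))
  id_of <- setNames(ids, schema$parameter)

  base <- s[, .(sample_id, admission_id,
                structure = if ("structure" %in% names(s)) structure else NA_character_,
                label)]

  if (nrow(s) && nrow(x$measurements)) {
    win <- s[, .(sample_id, admission_id, prediction_time,
                 window_start = prediction_time - observation_window)]
    m <- x$measurements[win,
                        on = .(admission_id, time > window_start, time <= prediction_time),
                        .(sample_id, parameter, value,
                          age = i.prediction_time - x.time),
                        nomatch = NULL]
  } else {
    m <- data.table(sample_id = character(), parameter = character(),
                    value = numeric(), age = numeric())
  }

  if (nrow(m)) {
    m[, hour_bin := pmax(as.integer(ceiling(age) - 1L), 0L)]
    hourly <- m[, .(value = mean(value)), by = .(sample_id, parameter, hour_bin)]
    ts <- hourly[, .(value = mean(value)),
                 by = .(sample_id, parameter,
                        timestep = ifelse(hour_bin < timestep_hours, "late", "early"))]
    wide <- dcast(ts, sample_id + parameter ~ timestep, value.var = "value")
    if (!"early" %in% names(wide)) wide[, early := NA_real_]
    if (!"late" %in% names(wide)) wide[, late := NA_real_]
    wide[, `:=`(obs_early = !is.na(early), obs_late = !is.na(late))]
    ## forward then backward imputation across the two timesteps
    wide[is.na(late) & !is.na(early), late := early]
    wide[is.na(early) & !is.na(late), early := late]
    wide[, feature := id_of[parameter]]
  } else {
    wide <- data.table(sample_id = character(), parameter = character(),
                       early = numeric(), late = numeric(),
                       obs_early = logical(), obs_late = logical(),
                       feature = character())
  }

  features <- copy(base)
  observed <- copy(base)
  for (fn in feat_names) {
    features[, (fn) := NA_real_]
    observed[, (fn) := FALSE]
  }
  if (nrow(wide)) {
    vdt <- wide[, .(sample_id, feature, value = late,
                    delta = late - early,
                    obs_value = obs_early | obs_late,
                    obs_delta = obs_early & obs_late)]
    for (p in seq_along(ids)) {
      sub <- vdt[feature == ids[p]]
      if (!nrow(sub)) next
      set(features, i = match(sub$sample_id, features$sample_id),
          j = ids[p], value = sub$value)
      set(features, i = match(sub$sample_id, features$sample_id),
          j = paste0(ids[p], "_delta"), value = sub$delta)
      set(observed, i = match(sub$sample_id, observed$sample_id),
          j = ids[p], value = sub$obs_value)
      set(observed, i = match(sub$sample_id, observed$sample_id),
          j = paste0(ids[p], "_delta"), value = sub$obs_delta)
    }
  }
  structure(list(features = features, observed = observed, schema = schema,
                 observation_window = observation_window),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d samples x %d features (%s)\n",
              nrow(x$features), 2 * nrow(x$schema),
              paste(unique(x$features$structure), collapse = ", ")))
  invisible(x)
}

#' Per-parameter missingness by framing structure
#'
#' Percentage of samples whose feature is missing, per parameter and
#' framing structure, computed from pre-imputation observability: a value
#' feature is missing when neither timestep held data; a delta feature is
#' missing (reported separately) when either timestep was unobserved.
#'
#' @param feature_sets a single `feature_set` or a list of them (one per
#'   framing structure).
#' @param parameters restrict to these display names (default: vital signs
#'   of the schema, the clinically interesting contrast; pass
#'   `schema$parameter` for all).
#' @return data.table (`parameter`, `feature_kind` = `"value"`/`"delta"`,
#'   one percentage column per structure).
#' @export
missingness_report <- function(feature_sets, parameters = NULL) {
  if (inherits(feature_sets, "feature_set")) feature_sets <- list(feature_sets)
  stopifnot(length(feature_sets) >= 1)
  schema <- feature_sets[[1]]$schema
  if (is.null(parameters)) parameters <- vital_parameters(schema)
  ids <- schema$id[match(parameters, schema$parameter)]

  one <- function(fs) {
    obs <- fs$observed
    structure_name <- unique(obs$structure)
    structure_name <- structure_name[!is.na(structure_name)]
    if (!length(structure_name)) structure_name <- "samples"
    rows <- lapply(seq_along(ids), function(p) {
      data.table(
        parameter = parameters[p],
        feature_kind = c("value", "delta"),
        structure = structure_name[1],
        missing_pct = c(100 * mean(!obs[[ids[p]]]),
                        100 * mean(!obs[[paste0(ids[p], "_delta")]]))
      )
    })
    rbindlist(rows)
  }
  long <- rbindlist(lapply(feature_sets, one))
  dcast(long, parameter + feature_kind ~ structure, value.var = "missing_pct")
}
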