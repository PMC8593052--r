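#' Synthetic inpatient cohort configuration
#'
#' Defines the study conditions the generator emulates: admission lengths of
#' stay drawn log-normally inside the cohort filter's admissible band, a
#' fixed fraction of admissions with a planted sepsis episode, irregular
#' laboratory sampling with heavy missingness, physician-driven EWS
#' assessment schedules with vitals recorded preferentially at assessment
#' times, and, for septic admissions, a linear pre-onset deterioration of
#' the vital signs and sepsis-relevant labs together with a qualifying
#' culture/antibiotic pair and a SOFA series that rises by more than two
#' points at onset.
#'
#' @param n_admissions number of admissions.
#' @param prevalence fraction of admissions with a planted episode, default
#'   0.0625; the planted count is deterministic,
#'   `floor(n_admissions * prevalence + 0.5)` (round half up).
#' @param los_meanlog,los_sdlog log-normal length-of-stay parameters
#'   (hours), defaults `log(72)` and `0.6`.
#' @param los_min,los_max stay bounds in hours, defaults 24 and 1200
#'   (the 24 h--50 d inclusion band).
#' @param ews_interval,ews_jitter mean and SD of hours between EWS
#'   assessments, defaults 8 and 2.
#' @param lab_interval mean hours between draws of a laboratory parameter,
#'   default 24.
#' @param abg_prob probability that an admission has arterial blood-gas
#'   parameters at all, default 0.35.
#' @param vitals_dropout per-vital probability of not being recorded at an
#'   EWS assessment, default 0.03 (temperature uses `temp_dropout`,
#'   default 0.12).
#' @param temp_dropout see above.
#' @param ramp_hours duration of the pre-onset drift of vitals and labs,
#'   default 60.
#' @param ramp_plateau hours before onset at which the drift saturates
#'   (compensated deterioration), default 16; windows ending anywhere in
#'   the plateau see comparable signal, so framing comparisons isolate the
#'   sampling policy rather than horizon-dependent signal strength.
#' @param sofa_pre_hours how long before onset the planted SOFA score rises
#'   from 0 to 1 (mild dysfunction preceding the acute rise), default 16.
#' @param si_culture_offset,si_abx_offset culture and antibiotic event
#'   times relative to the planted onset, defaults -2 and +1 hours.
#' @param decoy_rate fraction of negative admissions receiving a
#'   non-qualifying antibiotic or culture event, default 0.08.
#' @param neg_sofa_frac fraction of negative admissions with a constant
#'   mild SOFA score of 1 (chronic low-grade dysfunction that the
#'   dynamic-inclusion framing keeps sampling), default 0.7.
#' @param repeat_patient_frac fraction of patients contributing two
#'   admissions, default 0.1.
#' @param seed integer seed (mandatory; the cohort is fully reproducible
#'   from it).
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_admissions, prevalence = 0.0625,
                             los_meanlog = log(72), los_sdlog = 0.6,
                             los_min = 24, los_max = 1200,
                             ews_interval = 8, ews_jitter = 2,
                             lab_interval = 24, abg_prob = 0.35,
                             vitals_dropout = 0.03, temp_dropout = 0.12,
                             ramp_hours = 60, ramp_plateau = 16,
                             sofa_pre_hours = 16,
                             si_culture_offset = -2, si_abx_offset = 1,
                             decoy_rate = 0.08, neg_sofa_frac = 0.7,
                             repeat_patient_frac = 0.1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_admissions >= 1, prevalence >= 0, prevalence <= 1,
            los_min >= 0, los_max > los_min, ews_interval > 0,
            ramp_hours > 0, sofa_pre_hours > 0)
  pos_min_los <- max(48, ramp_hours + 24, sofa_pre_hours + 24,
                     20 + si_abx_offset + 4)
  if (prevalence > 0 && pos_min_los > los_max) {
    stop(sprintf("infeasible config: septic admissions need >= %g h of stay but los_max is %g h",
                 pos_min_los, los_max))
  }
  structure(list(
    n_admissions = as.integer(n_admissions), prevalence = prevalence,
    los_meanlog = los_meanlog, los_sdlog = los_sdlog,
    los_min = los_min, los_max = los_max,
    ews_interval = ews_interval, ews_jitter = ews_jitter,
    lab_interval = lab_interval, abg_prob = abg_prob,
    vitals_dropout = vitals_dropout, temp_dropout = temp_dropout,
    ramp_hours = ramp_hours, ramp_plateau = ramp_plateau,
    sofa_pre_hours = sofa_pre_hours,
    si_culture_offset = si_culture_offset, si_abx_offset = si_abx_offset,
    decoy_rate = decoy_rate, neg_sofa_frac = neg_sofa_frac,
    repeat_patient_frac = repeat_patient_frac,
    pos_min_los = pos_min_los, seed = as.integer(seed)
  ), class = "generator_config")
}

## per-parameter population baselines: mean, between-patient SD, and the
## total drift added by the end of the pre-onset ramp for septic admissions
parameter_dynamics <- function() {
  dt <- rbindlist(list(
    ## labs
    list("P(aB)-Hydrogen carbonate", 24.0, 2.0, -3.0),
    list("P(aB)-Potassium",          4.0, 0.30, 0.3),
    list("P-Bilirubin",              10.0, 4.0, 18.0),
    list("P(aB)-pO2",                11.5, 1.2, -2.5),
    list("B-Leukocytes",             7.5, 1.8, 7.0),
    list("P-Potassium",              4.0, 0.35, 0.3),
    list("P(aB)-pCO2",               5.3, 0.5, -0.6),
    list("B-Neutrophils",            4.5, 1.4, 6.0),
    list("P-Glucose",                6.0, 1.2, 1.5),
    list("P(aB)-pH",                 7.40, 0.03, -0.08),
    list("B-Platelets",              250.0, 50.0, -80.0),
    list("P-C-reactive protein",     8.0, 6.0, 120.0),
    list("P(aB)-Lactate",            1.1, 0.3, 2.5),
    list("P-Sodium",                 139.0, 2.5, 1.0),
    list("eGFR",                     85.0, 12.0, -25.0),
    list("P(aB)-Sodium",             139.0, 2.5, 1.0),
    list("P-Albumin",                38.0, 4.0, -6.0),
    list("P(aB)-Chloride",           103.0, 3.0, 2.0),
    list("P-Creatinine",             80.0, 15.0, 70.0),
    ## vitals
    list("Systolic blood pressure",  125.0, 12.0, -25.0),
    list("Diastolic blood pressure", 75.0, 8.0, -12.0),
    list("Pulse",                    75.0, 8.0, 30.0),
    list("Respiratory frequency",    16.0, 2.0, 8.0),
    list("SpO2",                     97.0, 1.0, -5.0),
    list("Temperature",              36.8, 0.3, 1.5)
  ))
  setnames(dt, c("parameter", "mean", "sd", "drift"))
  ## within-patient measurement noise
  dt[, noise := c(rep(NA_real_, 19),  14, 9, 10, 3.5, 2.5, 0.55)]
  dt[is.na(noise), noise := sd / 1.5]
  dt
}

#' Generate a synthetic cohort with planted sepsis episodes
#'
#' Produces a [cohort()] over the packaged 25-parameter schema together
#' with a per-admission ground-truth table and a precomputed SOFA series.
#' Positives carry, by construction, everything the Sepsis-3 labeler
#' requires: a qualifying culture/antibiotic pair around the planted onset,
#' a SOFA series rising from (at most) 1 to 4 at onset, and pre-onset drift
#' of the vital signs and sepsis-relevant labs. Vitals are recorded at EWS
#' assessment times (with small dropout), so framings triggered by EWS
#' assessments see far less vital-sign missingness than clock-driven ones.
#'
#' @param cfg a [generator_config()].
#' @return list with elements `cohort` (a [cohort()]), `ground_truth`
#'   (data.table `admission_id`, `planted`, `planted_onset_time`) and
#'   `sofa` (data.table `admission_id`, `time`, `score`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  schema <- default_parameter_schema()
  dyn <- parameter_dynamics()
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg, schema, dyn))
}

generate_cohort_impl <- function(cfg, schema, dyn) {
  n <- cfg$n_admissions
  n_pos <- as.integer(floor(n * cfg$prevalence + 0.5))  # round half up
  pos_idx <- if (n_pos > 0) sort(sample.int(n, n_pos)) else integer()
  is_pos <- seq_len(n) %in% pos_idx

  ## patients: a fraction contribute two admissions
  n_repeat <- min(floor(cfg$repeat_patient_frac * n), n %/% 2)
  n_patients <- n - n_repeat
  patient_pool <- sprintf("P%05d", seq_len(n_patients))
  patient_ids <- sample(c(patient_pool, patient_pool[seq_len(n_repeat)]))

  admission_ids <- sprintf("A%05d", seq_len(n))
  admit <- round(runif(n, 0, 24 * 365), 2)
  los <- pmin(pmax(rlnorm(n, cfg$los_meanlog, cfg$los_sdlog), cfg$los_min),
              cfg$los_max)
  los[is_pos] <- pmax(los[is_pos], cfg$pos_min_los)
  los <- round(los, 2)

  ## planted onsets on the hourly grid, >= 20 h in, >= 4 h before discharge
  onset_off <- rep(NA_real_, n)
  for (i in pos_idx) {
    hi <- floor(los[i]) - max(4, cfg$si_abx_offset + 1)
    support <- seq(20L, max(20L, as.integer(hi)))
    onset_off[i] <- support[sample.int(length(support), 1L)]
  }

  lab_pars <- dyn$parameter[1:19]
  abg_pars <- grep("^P\\(aB\\)", lab_pars, value = TRUE)
  common_labs <- setdiff(lab_pars, abg_pars)
  vital_pars <- dyn$parameter[20:25]
  dyn_mean <- setNames(dyn$mean, dyn$parameter)
  dyn_sd <- setNames(dyn$sd, dyn$parameter)
  dyn_drift <- setNames(dyn$drift, dyn$parameter)
  dyn_noise <- setNames(dyn$noise, dyn$parameter)

  mea_list <- vector("list", n)
  eve_list <- vector("list", n)
  sofa_list <- vector("list", n)

  for (i in seq_len(n)) {
    a0 <- admit[i]; a1 <- round(admit[i] + los[i], 2)
    onset <- if (is_pos[i]) a0 + onset_off[i] else NA_real_
    ramp_start <- if (is_pos[i]) onset - cfg$ramp_hours else NA_real_
    ## patients deteriorate with different intensity; a sizeable minority
    ## present atypically with a muted physiological response
    severity <- rlnorm(1, -0.2, 0.6)
    ## chronic low-grade organ dysfunction (SOFA 1 throughout) for a
    ## fraction of the negatives; these patients also destabilize more often
    mild_sofa <- !is_pos[i] && runif(1) < cfg$neg_sofa_frac
    ## transient non-septic deterioration episodes (fever, tachycardia from
    ## other causes) with a triangular time profile; both classes get them
    ep_rate <- if (is_pos[i]) los[i] / 120 else los[i] / 90
    n_ep <- rpois(1, ep_rate)
    ep_center <- if (n_ep > 0) runif(n_ep, a0 + 6, a1 - 6) else numeric()
    ep_halfwidth <- if (n_ep > 0) runif(n_ep, 6, 24) else numeric()
    ep_intensity <- if (n_ep > 0) runif(n_ep, 0.3, 1.1) else numeric()
    ## drift ramps linearly and saturates `ramp_plateau` hours before onset
    ## (compensated deterioration), so windows ending anywhere in the final
    ## plateau carry comparable signal regardless of the framing's horizon
    ramp_span <- max(cfg$ramp_hours - cfg$ramp_plateau, 1)
    drift_frac <- function(t) {
      f <- rep(0, length(t))
      if (is_pos[i]) {
        f <- severity * pmin(pmax((t - ramp_start) / ramp_span, 0), 1)
      }
      for (e in seq_len(n_ep)) {
        f <- f + ep_intensity[e] * pmax(0, 1 - abs(t - ep_center[e]) / ep_halfwidth[e])
      }
      pmin(f, 1.3)
    }
    baseline <- dyn_mean + rnorm(length(dyn_mean), 0, dyn_sd)
    names(baseline) <- names(dyn_mean)

    ## EWS assessment schedule, denser around deterioration for positives
    ews <- a0 + runif(1, 0.5, 3)
    while (tail(ews, 1) < a1 - 0.2) {
      step <- max(3, rnorm(1, cfg$ews_interval, cfg$ews_jitter))
      ews <- c(ews, tail(ews, 1) + step)
    }
    ews <- ews[ews <= a1 - 0.1]
    if (is_pos[i]) ews <- c(ews, onset - 8, onset - 3)
    ## clinicians reassess (twice) during a deterioration episode
    ep_ews <- rep(ep_center, 2) + runif(2 * n_ep, -0.5, 0.5) * rep(ep_halfwidth, 2)
    ews <- c(ews, ep_ews[ep_ews > a0 + 0.1 & ep_ews <= a1 - 0.1])
    ews <- round(sort(unique(ews)), 2)

    ## vitals recorded at EWS times, with per-vital dropout
    vit_rows <- list()
    for (v in vital_pars) {
      drop_p <- if (v == "Temperature") cfg$temp_dropout else cfg$vitals_dropout
      tt <- ews[runif(length(ews)) > drop_p]
      if (!length(tt)) next
      val <- baseline[v] + dyn_noise[v] * rnorm(length(tt)) +
        dyn_drift[v] * drift_frac(tt)
      vit_rows[[v]] <- data.table(time = tt, parameter = v, value = val)
    }
    ## a few vitals off the EWS schedule
    n_extra <- rpois(1, los[i] / 48)
    if (n_extra > 0) {
      tt <- round(runif(n_extra, a0, a1), 2)
      vv <- sample(vital_pars, n_extra, replace = TRUE)
      vit_rows[["extra"]] <- data.table(
        time = tt, parameter = vv,
        value = baseline[vv] + dyn_noise[vv] * rnorm(n_extra) +
          dyn_drift[vv] * drift_frac(tt))
    }

    ## laboratory draws at irregular ~daily intervals
    has_abg <- runif(1) < cfg$abg_prob
    lab_rows <- list()
    for (p in c(common_labs, if (has_abg) abg_pars)) {
      tt <- a0 + runif(1, 1, cfg$lab_interval / 2)
      while (tail(tt, 1) < a1 - 1) {
        tt <- c(tt, tail(tt, 1) + max(6, rnorm(1, cfg$lab_interval,
                                               cfg$lab_interval / 4)))
      }
      tt <- round(tt[tt <= a1], 2)
      if (is_pos[i]) {
        ## an extra draw during deterioration, as clinicians react
        tt <- sort(unique(c(tt, round(onset - runif(1, 1, 6), 2))))
      }
      if (!length(tt)) next
      val <- baseline[p] + dyn_noise[p] * rnorm(length(tt)) +
        dyn_drift[p] * drift_frac(tt)
      lab_rows[[p]] <- data.table(time = tt, parameter = p, value = val)
    }

    mm <- rbindlist(c(vit_rows, lab_rows))
    if (nrow(mm)) {
      mm[parameter == "SpO2", value := pmin(pmax(value, 70), 100)]
      mm[parameter != "SpO2", value := pmax(value, 0.01)]
      mm[, `:=`(admission_id = admission_ids[i], value = round(value, 3),
                time = pmin(pmax(time, a0), a1))]
      mea_list[[i]] <- mm
    }

    ## events: EWS assessments + SI pair / decoys
    ev <- data.table(time = ews, kind = "ews_assessment")
    if (is_pos[i]) {
      ev <- rbind(ev, data.table(
        time = round(c(onset + cfg$si_culture_offset, onset + cfg$si_abx_offset), 2),
        kind = c("culture_sample", "antibiotic_administration")))
    } else if (runif(1) < cfg$decoy_rate) {
      if (los[i] > 90 && runif(1) < 0.5) {
        t0 <- round(runif(1, a0 + 1, a1 - 85), 2)
        ev <- rbind(ev, data.table(
          time = c(t0, round(t0 + 80, 2)),
          kind = c("culture_sample", "antibiotic_administration")))
      } else {
        ev <- rbind(ev, data.table(time = round(runif(1, a0 + 1, a1 - 1), 2),
                                   kind = "antibiotic_administration"))
      }
    }
    ev[, admission_id := admission_ids[i]]
    eve_list[[i]] <- ev

    ## precomputed SOFA series on the hourly grid
    grid <- sofa_grid(a0, a1)
    score <- if (is_pos[i]) {
      ifelse(grid < onset - cfg$sofa_pre_hours, 0L,
             ifelse(grid < onset, 1L, 4L))
    } else if (mild_sofa) {
      rep(1L, length(grid))
    } else {
      rep(0L, length(grid))
    }
    sofa_list[[i]] <- data.table(admission_id = admission_ids[i],
                                 time = grid, score = as.integer(score))
  }

  ## ground truth stores absolute onset; discharge rounding matches the loop
  admissions <- data.table(
    admission_id = admission_ids, patient_id = patient_ids,
    admit_time = admit, discharge_time = round(admit + los, 2))
  co <- cohort(admissions, rbindlist(mea_list), rbindlist(eve_list),
               schema = schema)
  gt <- data.table(admission_id = admission_ids,
                   planted = as.integer(is_pos),
                   planted_onset_time = admit + onset_off)
  list(cohort = co, ground_truth = gt, sofa = rbindlist(sofa_list))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a generated cohort
#'
#' @param x a `cohort`.
#' @param ground_truth the generator's ground-truth table.
#' @return a `cohort_summary` list: counts, planted prevalence,
#'   length-of-stay summary, events by kind and per-parameter measurement
#'   density (measurements per admission).
#' @export
describe_cohort <- function(x, ground_truth = NULL) {
  stopifnot(inherits(x, "cohort"))
  n_adm <- nrow(x$admissions)
  los <- x$admissions$discharge_time - x$admissions$admit_time
  dens <- if (nrow(x$measurements)) {
    d <- x$measurements[, .(n_meas = .N), by = parameter]
    d[, per_admission := round(n_meas / n_adm, 2)]
    setorder(d, parameter)[]
  } else {
    data.table(parameter = character(), n_meas = integer(),
               per_admission = numeric())
  }
  structure(list(
    n_admissions = n_adm,
    n_patients = length(unique(x$admissions$patient_id)),
    n_measurements = nrow(x$measurements),
    n_events = nrow(x$events),
    prevalence = if (!is.null(ground_truth) && n_adm > 0) {
      mean(as.data.table(ground_truth)$planted)
    } else NA_real_,
    los_hours = if (n_adm > 0) {
      c(min = min(los), median = median(los), max = max(los))
    } else c(min = 0, median = 0, max = 0),
    events_by_kind = if (nrow(x$events)) {
      x$events[, .N, by = kind][order(kind)]
    } else data.table(kind = character(), N = integer()),
    measurement_density = dens
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d admissions / %d patients, %d measurements, %d events\n",
              x$n_admissions, x$n_patients, x$n_measurements, x$n_events))
  cat(sprintf("  planted prevalence: %s\n",
              ifelse(is.na(x$prevalence), "n/a", sprintf("%.4f", x$prevalence))))
  cat(sprintf("  length of stay (h): min %.1f / median %.1f / max %.1f\n",
              x$los_hours["min"], x$los_hours["median"], x$los_hours["max"]))
  invisible(x)
}
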