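## tiny hand-built cohorts and independent brute-force oracles shared
## across the test files

suppressMessages(library(data.table))

tiny_admissions <- function() {
  data.frame(
    admission_id = c("A1", "A2"),
    patient_id = c("P1", "P2"),
    admit_time = c(0, 100),
    discharge_time = c(48, 172)
  )
}

tiny_cohort <- function() {
  mea <- data.frame(
    admission_id = rep(c("A1", "A2"), c(6, 4)),
    time = c(1, 2, 10, 20, 30, 40, 101, 120, 150, 170),
    parameter = c("Pulse", "Pulse", "Temperature", "B-Platelets", "SpO2",
                  "P-Creatinine", "Pulse", "Temperature", "SpO2", "Pulse"),
    value = c(80, 90, 37.1, 220, 97, 80, 72, 36.8, 98, 75)
  )
  eve <- data.frame(
    admission_id = c("A1", "A1", "A2"),
    time = c(5, 25, 110),
    kind = c("ews_assessment", "culture_sample", "antibiotic_administration")
  )
  cohort(tiny_admissions(), mea, eve)
}

## random single-admission event sets for the Sepsis-3 pairing oracle
random_events <- function(n_cultures, n_abx, n_ews, horizon = 200) {
  kinds <- c(rep("culture_sample", n_cultures),
             rep("antibiotic_administration", n_abx),
             rep("ews_assessment", n_ews))
  data.frame(
    admission_id = rep("A1", length(kinds)),
    time = round(runif(length(kinds), 0, horizon), 2),
    kind = kinds
  )
}

## brute-force Sepsis-3 oracle: enumerate all pairs and all window grid
## points, entirely independently of the package's vectorized path
oracle_si_pairs <- function(events, cfg = sepsis3_config()) {
  cul <- sort(events$time[events$kind == "culture_sample"])
  abx <- sort(events$time[events$kind == "antibiotic_administration"])
  out <- list()
  for (ct in cul) for (at in abx) {
    ok <- (ct <= at && at - ct <= cfg$max_culture_to_abx) ||
      (at < ct && ct - at <= cfg$max_abx_to_culture)
    if (ok) out[[length(out) + 1]] <- c(index = min(ct, at))
  }
  sort(unname(vapply(out, `[[`, numeric(1), "index")))
}

oracle_onset <- function(si_index_times, grid_times, grid_scores,
                         cfg = sepsis3_config()) {
  best <- Inf
  for (idx in si_index_times) {
    win <- which(grid_times >= idx - cfg$sofa_window_before &
                   grid_times <= idx + cfg$sofa_window_after)
    for (j in win) {
      baseline <- min(grid_scores[win[win <= j]])
      if (grid_scores[j] - baseline >= cfg$sofa_delta_threshold) {
        best <- min(best, grid_times[j])
        break
      }
    }
  }
  if (is.finite(best)) best else NA_real_
}

## brute-force framing oracle: enumerate every candidate prediction time
## and test label membership directly
oracle_sliding <- function(admit, discharge, onset, cfg) {
  times <- numeric(0)
  t <- admit + cfg$observation_window
  while (t <= discharge + 1e-9) {
    times <- c(times, t)
    t <- t + cfg$window_shift
  }
  if (!is.na(onset)) times <- times[times < onset]
  labels <- vapply(times, function(tt) {
    if (is.na(onset)) return(0L)
    lo <- tt + cfg$lead_window
    as.integer(onset > lo && onset <= lo + cfg$prediction_window)
  }, integer(1))
  list(times = times, labels = labels)
}

## direct hand-binning ACE oracle
oracle_ace <- function(labels, probs, n_bins) {
  edges <- seq(0, 1, length.out = n_bins + 1)
  diffs <- c()
  for (b in seq_len(n_bins)) {
    inb <- if (b == 1) probs <= edges[2] else
      probs > edges[b] & probs <= edges[b + 1]
    if (any(inb)) {
      diffs <- c(diffs, abs(mean(labels[inb]) - mean(probs[inb])))
    }
  }
  100 * mean(diffs)
}
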