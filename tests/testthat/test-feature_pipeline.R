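sample_row <- function(id = "S1", adm = "A1", tp = 24) {
  data.frame(sample_id = id, admission_id = adm, prediction_time = tp,
             label = 0L, structure = "sliding_window")
}

test_that("observation extraction is half-open and never looks forward", {
  adm <- data.frame(admission_id = "A1", patient_id = "P1",
                    admit_time = 0, discharge_time = 48)
  mea <- data.frame(admission_id = "A1",
                    time = c(12.0, 20, 24.0, 24.1),
                    parameter = "Pulse", value = c(70, 80, 90, 999))
  co <- cohort(adm, mea)
  w <- extract_observation(co, sample_row(tp = 24), observation_window = 12)
  expect_setequal(w$value, c(80, 90))      # 24.1 excluded, 24.0 included,
  expect_false(12.0 %in% w$time)           # exactly window-start excluded

  ## window clipped by admission start
  w2 <- extract_observation(co, sample_row(tp = 13), observation_window = 12)
  expect_setequal(w2$value, 70)
})

test_that("hourly means collapse multiple values within a bin", {
  raw <- data.frame(admission_id = "A1", time = c(23.2, 23.8, 20.5),
                    parameter = "Pulse", value = c(80, 90, 60))
  h <- hourly_mean(raw, prediction_time = 24)
  expect_equal(h[h$hour_bin == 0]$value, 85)
  expect_equal(h[h$hour_bin == 3]$value, 60)
  expect_equal(nrow(hourly_mean(raw[0, ], 24)), 0)
})

test_that("timestep binning, imputation and assembly produce the doubled feature set", {
  sch <- default_parameter_schema()
  h <- data.frame(parameter = "Pulse", hour_bin = c(0, 1, 2),
                  value = c(1, 2, 3))
  grid <- bin_timesteps(h, sch)
  expect_equal(unname(grid$late["Pulse"]), 2)
  expect_true(is.na(grid$early["Pulse"]))

  imp <- impute_forward_backward(grid)
  expect_equal(unname(imp$early["Pulse"]), 2)   # backward fill
  expect_false(imp$obs_early[["Pulse"]])        # observability preserved
  ## idempotent
  expect_identical(impute_forward_backward(imp), imp)

  fv <- assemble_features(imp, sch)
  expect_length(fv, 50)
  expect_equal(unname(fv["Pulse"]), 2)
  expect_equal(unname(fv["Pulse_delta"]), 0)    # single imputed source

  ## explicit early/late pair
  h2 <- data.frame(parameter = rep("Pulse", 2), hour_bin = c(2, 8),
                   value = c(10, 4))
  fv2 <- assemble_features(impute_forward_backward(bin_timesteps(h2, sch)), sch)
  expect_equal(unname(fv2["Pulse"]), 10)
  expect_equal(unname(fv2["Pulse_delta"]), 6)

  ## both-missing parameters stay missing
  expect_true(is.na(fv["SpO2"]))
})

test_that("feature count is twice the schema size for any schema", {
  for (k in c(1, 3, 25)) {
    sch <- parameter_schema(paste0("param", seq_len(k)), rep("u", k),
                            rep("lab", k))
    grid <- bin_timesteps(data.frame(parameter = "param1", hour_bin = 0,
                                     value = 1), sch)
    expect_length(assemble_features(impute_forward_backward(grid), sch), 2 * k)
  }
})

test_that("vectorized featurization agrees with the per-sample path", {
  g <- generate_cohort(generator_config(n_admissions = 15, seed = 31))
  suppressMessages(co <- filter_admissions(g$cohort))
  out <- label_cohort(co, sofa = g$sofa)
  samples <- frame_cohort(co, out, framing_config("sliding_window"))
  samples <- samples[seq(1, nrow(samples), by = 7)]
  fs <- featurize_samples(co, samples)
  for (i in seq_len(nrow(samples))) {
    raw <- extract_observation(co, samples[i])
    grid <- bin_timesteps(hourly_mean(raw, samples$prediction_time[i]),
                          co$schema)
    fv <- assemble_features(impute_forward_backward(grid), co$schema)
    got <- unlist(fs$features[i, names(fv), with = FALSE])
    expect_equal(as.numeric(got), as.numeric(fv))
    obs_got <- unlist(fs$observed[i, names(fv), with = FALSE])
    expect_equal(as.logical(obs_got), as.logical(attr(fv, "observed")))
  }
})

test_that("poisoning data after the prediction time changes no feature", {
  g <- generate_cohort(generator_config(n_admissions = 12, seed = 8))
  suppressMessages(co <- filter_admissions(g$cohort))
  out <- label_cohort(co, sofa = g$sofa)
  samples <- frame_cohort(co, out, framing_config("sliding_window"))
  fs <- featurize_samples(co, samples)

  withr::local_seed(3)
  for (i in sample(nrow(samples), 8)) {
    s <- samples[i]
    poisoned <- co
    pm <- data.table::copy(co$measurements)
    pm[time > s$prediction_time, value := 1e6]   # sentinel in the future
    poisoned$measurements <- pm
    fs2 <- featurize_samples(poisoned, s)
    expect_equal(as.data.frame(fs2$features),
                 as.data.frame(fs$features[sample_id == s$sample_id]))
  }
})

test_that("missingness is reported per parameter from pre-imputation observability", {
  adm <- data.frame(admission_id = "A1", patient_id = "P1",
                    admit_time = 0, discharge_time = 48)
  mea <- data.frame(admission_id = "A1", time = c(20, 23),
                    parameter = "Pulse", value = c(70, 80))
  co <- cohort(adm, mea)
  fs <- featurize_samples(co, sample_row(tp = 24))
  rep <- missingness_report(fs, parameters = c("Pulse", "SpO2"))
  expect_equal(rep[parameter == "Pulse" & feature_kind == "value"]$sliding_window, 0)
  ## only the late timestep was observed: the delta counts as missing
  expect_equal(rep[parameter == "Pulse" & feature_kind == "delta"]$sliding_window, 100)
  ## a never-measured parameter is 100% missing
  expect_equal(rep[parameter == "SpO2" & feature_kind == "value"]$sliding_window, 100)
})
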