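adm1 <- function(admit = 0, discharge = 48, id = "A1") {
  data.frame(admission_id = id, patient_id = "P1",
             admit_time = admit, discharge_time = discharge)
}
outc <- function(onset = NA_real_, id = "A1") {
  data.frame(admission_id = id, onset_time = onset, si_index_time = onset)
}

test_that("fixed time to onset emits one sample per admission or drops it", {
  cfg <- framing_config("fixed_time_to_onset")
  ## positive: prediction 12 h before onset
  s <- frame_fixed_time_to_onset(adm1(0, 60), outc(40), cfg)
  expect_equal(nrow(s), 1)
  expect_equal(s$prediction_time, 28)
  expect_equal(s$label, 1L)

  ## onset too early: the sample would precede admission
  expect_equal(nrow(frame_fixed_time_to_onset(adm1(0, 60), outc(6), cfg)), 0)

  ## negative: seeded uniform time inside the admission, reproducible
  s1 <- withr::with_seed(9, frame_fixed_time_to_onset(adm1(), outc(), cfg))
  s2 <- withr::with_seed(9, frame_fixed_time_to_onset(adm1(), outc(), cfg))
  expect_equal(s1$prediction_time, s2$prediction_time)
  expect_equal(s1$label, 0L)
  expect_true(s1$prediction_time > 0 && s1$prediction_time <= 48)
})

test_that("sliding window enumerates the shift grid with censoring and labels", {
  cfg <- framing_config("sliding_window")
  neg <- frame_sliding_window(adm1(), outc(), cfg)
  expect_equal(neg$prediction_time, seq(12, 48, by = 6))
  expect_true(all(neg$label == 0L))

  pos <- frame_sliding_window(adm1(), outc(30), cfg)
  expect_equal(pos$prediction_time, c(12, 18, 24))
  expect_equal(pos$label, c(0L, 1L, 1L))

  ## an admission shorter than the observation window yields nothing
  expect_equal(nrow(frame_sliding_window(adm1(0, 10), outc(), cfg)), 0)

  ## boundary tie: onset exactly at the end of the prediction window is positive
  tie <- frame_sliding_window(adm1(0, 13), outc(24.0), cfg)
  expect_equal(tie$label, 1L)
})

test_that("dynamic inclusion keeps the sliding grid from the first SOFA > 0 hour", {
  cfg <- framing_config("sliding_window_dynamic")
  swcfg <- framing_config("sliding_window")
  a <- adm1()

  ## never ill: no samples
  s0 <- sofa_from_table(0, 0, 0, 48)
  expect_equal(nrow(frame_sliding_dynamic(a, outc(), s0, cfg)), 0)

  ## ill from the start: identical to plain sliding window
  s1 <- sofa_from_table(0, 1, 0, 48)
  dyn <- frame_sliding_dynamic(a, outc(), s1, cfg)
  sw <- frame_sliding_window(a, outc(), swcfg)
  expect_equal(dyn$prediction_time, sw$prediction_time)
  expect_equal(dyn$label, sw$label)

  ## SOFA first positive at hour 20: sampling resumes at the next grid time
  s2 <- sofa_from_table(c(0, 20), c(0, 1), 0, 48)
  dyn2 <- frame_sliding_dynamic(a, outc(), s2, cfg)
  expect_equal(dyn2$prediction_time, seq(24, 48, by = 6))
})

test_that("on clinical demand samples exactly at EWS assessments", {
  cfg <- framing_config("on_clinical_demand")
  ews <- function(times) {
    data.frame(admission_id = "A1", time = times, kind = "ews_assessment")
  }
  neg <- frame_on_clinical_demand(adm1(), outc(), ews(c(8, 20, 33)), cfg)
  expect_equal(neg$prediction_time, c(8, 20, 33))
  expect_true(all(neg$label == 0L))

  ## onset 28 within (20, 32] of the assessment at 20
  pos <- frame_on_clinical_demand(adm1(), outc(28), ews(20), cfg)
  expect_equal(pos$label, 1L)

  ## non-EWS events and empty trigger sets yield nothing
  other <- data.frame(admission_id = "A1", time = 10, kind = "culture_sample")
  expect_equal(nrow(frame_on_clinical_demand(adm1(), outc(), other, cfg)), 0)
})

test_that("sample counts and labels match exhaustive enumeration on random admissions", {
  withr::local_seed(77)
  cfg <- framing_config("sliding_window")
  for (rep in 1:1000) {
    admit <- round(runif(1, 0, 100), 2)
    los <- round(runif(1, 4, 200), 2)
    onset <- if (runif(1) < 0.4) round(admit + runif(1) * los, 2) else NA_real_
    a <- adm1(admit, admit + los)
    got <- frame_sliding_window(a, outc(onset), cfg)
    want <- oracle_sliding(admit, admit + los, onset, cfg)
    expect_equal(got$prediction_time, want$times)
    expect_equal(got$label, want$labels)
  }
})

test_that("dynamic samples are a subset of sliding samples with identical positives", {
  withr::local_seed(78)
  sw_cfg <- framing_config("sliding_window")
  dy_cfg <- framing_config("sliding_window_dynamic")
  for (rep in 1:300) {
    admit <- round(runif(1, 0, 50), 2)
    los <- round(runif(1, 24, 200), 2)
    onset <- if (runif(1) < 0.5) admit + sample(13:floor(los), 1) else NA_real_
    a <- adm1(admit, admit + los)
    ## step SOFA trace; positives become mildly ill 16 h before onset
    ill_from <- if (!is.na(onset)) max(0, onset - admit - 16) else
      round(runif(1, 0, los), 2)
    st <- unique(c(0, ill_from))
    sc <- if (length(st) == 1) 1L else c(0L, 1L)
    series <- sofa_from_table(admit + st, sc, admit, admit + los)
    sw <- frame_sliding_window(a, outc(onset), sw_cfg)
    dyn <- frame_sliding_dynamic(a, outc(onset), series, dy_cfg)
    expect_true(all(dyn$prediction_time %in% sw$prediction_time))
    merged <- merge(dyn, sw, by = "prediction_time")
    expect_equal(merged$label.x, merged$label.y)
    expect_setequal(dyn$prediction_time[dyn$label == 1L],
                    sw$prediction_time[sw$label == 1L])
  }
})

test_that("class balance renders counts and the 1:N ratio", {
  mk <- function(pos, neg) {
    data.frame(label = rep(c(1L, 0L), c(pos, neg)))
  }
  b <- class_balance(mk(2, 30))
  expect_equal(b$ratio_text, "1:15")
  expect_equal(b$positives, 2)

  none <- class_balance(mk(0, 10))
  expect_true(is.na(none$ratio_text))
  expect_equal(none$negatives, 10)

  expect_equal(class_balance(mk(5, 0))$ratio_text, "1:0")
})

test_that("cohort framing is deterministic and reports class balance", {
  g <- generate_cohort(generator_config(n_admissions = 40, seed = 15))
  suppressMessages(co <- filter_admissions(g$cohort))
  out <- label_cohort(co, sofa = g$sofa)
  cfg <- framing_config("fixed_time_to_onset", seed = 4)
  s1 <- frame_cohort(co, out, cfg)
  s2 <- frame_cohort(co, out, cfg)
  expect_equal(data.frame(s1), data.frame(s2))
  expect_equal(nrow(s1), nrow(co$admissions) -
                 sum(!is.na(out$onset_time) &
                       out$onset_time - 12 < co$admissions$admit_time))
  expect_s3_class(attr(s1, "class_balance"), "class_balance")
})
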