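test_that("stratified Brier matches hand arithmetic and degenerate forms", {
  b <- stratified_brier(c(1, 0), c(0.7, 0.2))
  expect_equal(b$brier_pos_x100, 9)
  expect_equal(b$brier_neg_x100, 4)

  perfect <- stratified_brier(c(1, 1, 0), c(1, 1, 0))
  expect_equal(perfect$brier_pos_x100, 0)
  expect_equal(perfect$brier_neg_x100, 0)

  flat <- stratified_brier(c(1, 0, 1, 0), rep(0.5, 4))
  expect_equal(flat$brier_pos_x100, 25)
  expect_equal(flat$brier_neg_x100, 25)

  ## absent class is undefined, empty input errors
  expect_true(is.na(stratified_brier(c(1, 1), c(0.9, 0.8))$brier_neg_x100))
  expect_error(stratified_brier(numeric(), numeric()), "empty")
})

test_that("the Brier decomposition identity holds to machine precision", {
  withr::local_seed(11)
  for (rep in 1:200) {
    n <- sample(5:200, 1)
    labels <- rbinom(n, 1, runif(1, 0.1, 0.9))
    if (length(unique(labels)) < 2) next
    probs <- runif(n)
    s <- stratified_brier(labels, probs)
    pi_hat <- mean(labels)
    overall <- mean((probs - labels)^2)
    expect_equal(pi_hat * s$brier_pos_x100 / 100 +
                   (1 - pi_hat) * s$brier_neg_x100 / 100,
                 overall, tolerance = 1e-12)
  }
})

test_that("ACE matches the hand-binning example and a brute-force oracle", {
  ## two bins worked by hand: |0 - 0.15| and |0.5 - 0.85| -> 25%
  expect_equal(ace(c(1, 0, 0, 0), c(0.9, 0.8, 0.1, 0.2), n_bins = 2), 25)

  ## predictions equal to each bin's event rate are perfectly calibrated
  expect_equal(ace(c(1, 0, 1, 0), c(0.5, 0.5, 0.5, 0.5), n_bins = 10), 0)
  expect_equal(ace(c(1, 1), c(1, 1), n_bins = 10), 0)

  withr::local_seed(12)
  for (rep in 1:500) {
    n <- sample(2:200, 1)
    labels <- rbinom(n, 1, 0.3)
    probs <- round(runif(n), 3)
    bins <- sample(2:20, 1)
    expect_equal(ace(labels, probs, bins), oracle_ace(labels, probs, bins),
                 tolerance = 1e-12)
  }
})

test_that("calibration bins partition all observations", {
  withr::local_seed(13)
  probs <- runif(500)
  labels <- rbinom(500, 1, probs)
  cb <- calibration_bins(labels, probs, n_bins = 10)
  expect_equal(sum(cb$count), 500)
  expect_equal(cb$lo, seq(0, 0.9, by = 0.1))
  ## probability zero lands in the first bin
  cb0 <- calibration_bins(c(0, 1), c(0, 1), n_bins = 4)
  expect_equal(cb0[cb0$bin == 1]$count, 1)
})

test_that("AUROC and AUPRC honour perfect, inverted and tied rankings", {
  expect_equal(auroc(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(auroc(c(1, 0), c(0, 1)), 0)
  expect_equal(auprc(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_error(auroc(c(1, 1), c(0.5, 0.6)), "both classes")

  ## midrank tie handling agrees with an established implementation
  withr::local_seed(14)
  for (rep in 1:100) {
    n <- sample(10:80, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    probs <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    ref <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(labels, probs), ref, tolerance = 1e-12)
  }
})

test_that("AUPRC agrees with explicit threshold counting", {
  withr::local_seed(15)
  for (rep in 1:200) {
    n <- sample(5:100, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    probs <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    ## oracle: precision/recall by direct counting at each distinct score,
    ## step-integrated over increasing recall
    th <- sort(unique(probs), decreasing = TRUE)
    prev_r <- 0; ap <- 0
    for (t in th) {
      sel <- probs >= t
      prec <- sum(labels[sel]) / sum(sel)
      rec <- sum(labels[sel]) / sum(labels)
      ap <- ap + (rec - prev_r) * prec
      prev_r <- rec
    }
    expect_equal(auprc(labels, probs), ap, tolerance = 1e-12)
  }
})

test_that("random predictions land at the null values of both metrics", {
  withr::local_seed(16)
  labels <- rbinom(10000, 1, 0.5)
  probs <- runif(10000)
  expect_lt(abs(auroc(labels, probs) - 0.5), 0.02)
  expect_lt(abs(auprc(labels, probs) - mean(labels)), 0.02)

  ## imbalanced null: AUPRC tracks prevalence
  labels2 <- rbinom(10000, 1, 0.05)
  probs2 <- runif(10000)
  expect_lt(abs(auprc(labels2, probs2) - mean(labels2)), 0.02)
})

test_that("AUROC is invariant under monotone transforms, ACE is not", {
  withr::local_seed(17)
  probs <- runif(400)
  labels <- rbinom(400, 1, probs)          # calibrated scores
  squashed <- probs^3                      # monotone but miscalibrated
  expect_equal(auroc(labels, squashed), auroc(labels, probs))
  expect_gt(ace(labels, squashed) - ace(labels, probs), 5)
})

test_that("fold summaries follow the t-interval", {
  s <- summarize_folds(c(0.5, 0.5, 0.5))
  expect_equal(s$lo, s$hi)

  v <- c(0, 1, 0, 1, 0)
  s2 <- summarize_folds(v)
  half <- qt(0.975, 4) * sd(v) / sqrt(5)
  expect_equal(s2$mean, 0.4)
  expect_equal(s2$hi, 0.4 + half)
  expect_error(summarize_folds(0.7), "at least two")
})

test_that("grouped folds give 80/10/10 role splits with disjoint test portions", {
  plan <- split_folds(sprintf("P%03d", 1:100), k = 5, seed = 2)
  for (i in 1:5) {
    f <- plan[fold == i]
    expect_equal(sort(unique(f$patient_id)), sort(sprintf("P%03d", 1:100)))
    expect_equal(sum(f$role == "train"), 80)
    expect_equal(sum(f$role == "validation"), 10)
    expect_equal(sum(f$role == "test"), 10)
    ## one role per patient within a fold
    expect_equal(anyDuplicated(f$patient_id), 0)
  }
  tests <- lapply(1:5, function(i) plan[fold == i & role == "test"]$patient_id)
  expect_equal(length(unique(unlist(tests))), 50)  # pairwise disjoint

  expect_equal(plan, split_folds(sprintf("P%03d", 1:100), k = 5, seed = 2))
  expect_error(split_folds(c("a", "b"), k = 5, seed = 1), "at least 10")
})

test_that("model adapters separate, reproduce and reject degenerate input", {
  withr::local_seed(18)
  n <- 120
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(x[, 1] + x[, 2] > 0)           # separable signal
  x[sample(length(x), 40)] <- NA                 # with missing entries
  for (fam in c("extra_trees", "random_forest", "xgboost",
                "logistic_regression")) {
    p <- train_predict(model_spec(fam), x, y, x)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(auroc(y, as.numeric(p)), 0.9)
    p2 <- train_predict(model_spec(fam), x, y, x)
    expect_equal(as.numeric(p), as.numeric(p2))  # fixed-seed determinism
  }
  expect_error(train_predict(model_spec("xgboost"), x, rep(1L, n), x),
               "degenerate")
  expect_error(model_spec("lightgbm"), "unsupported")
})

test_that("labels independent of features give chance-level discrimination", {
  withr::local_seed(19)
  n <- 400
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(n, 1, 0.5)
  p <- train_predict(model_spec("xgboost", params = list(eta = 0.3)),
                     x[1:300, ], y[1:300], x[301:400, ])
  expect_equal(auroc(y[301:400], as.numeric(p)), 0.5, tolerance = 0.12)
})

test_that("the benchmark grid runs end to end and marks undefined cells", {
  g <- generate_cohort(generator_config(n_admissions = 80, seed = 23))
  suppressMessages(co <- filter_admissions(g$cohort))
  out <- label_cohort(co, sofa = g$sofa)
  cfgs <- list(fixed = framing_config("fixed_time_to_onset", seed = 1),
               demand = framing_config("on_clinical_demand"))
  specs <- list(xgb = model_spec("xgboost"),
                logit = model_spec("logistic_regression"))
  plan <- split_folds(co$admissions$patient_id, k = 5, seed = 6)
  res <- suppressWarnings(
    benchmark_matrix(co, out, cfgs, specs, plan, sofa = g$sofa))
  expect_equal(sort(unique(res$folds$framing)), c("demand", "fixed"))
  expect_equal(nrow(res$folds), 2 * 2 * 5 * 5)   # framings x models x folds x metrics
  expect_true(all(res$folds$value >= 0 | is.na(res$folds$value)))
  expect_equal(nrow(res$class_balance), 2)
  ## patient-level leakage guard: within a fold each patient has one role
  for (i in 1:5) {
    f <- plan[fold == i]
    expect_equal(anyDuplicated(f$patient_id), 0)
  }
})
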