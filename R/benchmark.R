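#' Benchmark framing structures against model families
#'
#' Runs the full grid: for every framing configuration, the cohort is
#' converted to samples and features once; for every fold of the plan and
#' every model family, a model is trained on the training patients (with
#' the validation patients available for early stopping) and evaluated on
#' the test patients with AUPRC, AUROC, stratified Brier (x100, per class)
#' and ACE. A cell whose test split lacks one of the classes is marked
#' undefined (`NA`) and the run continues.
#'
#' @param x a filtered, labeled `cohort`.
#' @param outcomes output of [label_cohort()].
#' @param framing_configs named list of [framing_config()]s.
#' @param model_specs named list of [model_spec()]s.
#' @param fold_plan a [split_folds()] plan over the cohort's patients.
#' @param sofa long SOFA table, required when a dynamic-inclusion framing
#'   is present.
#' @param n_bins calibration bins for ACE, default 10.
#' @return a `benchmark_result` list:
#'   * `folds`: data.table (`framing`, `model`, `fold`, `metric`, `value`);
#'   * `summary`: data.table (`framing`, `model`, `metric`, `mean`, `lo`,
#'     `hi`);
#'   * `class_balance`: data.table (`framing`, `positives`, `negatives`,
#'     `ratio_text`, `ratio_n`, `sample_prevalence`).
#' @export
benchmark_matrix <- function(x, outcomes, framing_configs, model_specs,
                             fold_plan, sofa = NULL, n_bins = 10) {
  stopifnot(inherits(x, "cohort"), inherits(fold_plan, "fold_plan"))
  stopifnot(length(names(framing_configs)) == length(framing_configs),
            length(names(model_specs)) == length(model_specs))
  k <- attr(fold_plan, "k")
  pat_of <- x$admissions[, .(admission_id, patient_id)]

  fold_rows <- list(); bal_rows <- list()
  for (fr_name in names(framing_configs)) {
    cfg <- framing_configs[[fr_name]]
    samples <- frame_cohort(x, outcomes, cfg, sofa = sofa)
    bal <- class_balance(samples)
    bal_rows[[fr_name]] <- data.table(
      framing = fr_name, positives = bal$positives, negatives = bal$negatives,
      ratio_text = bal$ratio_text,
      ratio_n = if (bal$positives > 0) bal$negatives / bal$positives else NA_real_,
      sample_prevalence = if (nrow(samples)) mean(samples$label) else NA_real_
    )
    if (!nrow(samples)) next
    fs <- featurize_samples(x, samples,
                            observation_window = cfg$observation_window)
    xm <- feature_matrix(fs)
    meta <- fs$features[, .(sample_id, admission_id, label)]
    meta <- pat_of[meta, on = "admission_id"]

    for (fold_i in seq_len(k)) {
      assign_dt <- fold_plan[fold == fold_i]
      role_of <- setNames(assign_dt$role, assign_dt$patient_id)
      roles <- role_of[meta$patient_id]
      tr <- which(roles == "train"); va <- which(roles == "validation")
      te <- which(roles == "test")
      y_tr <- meta$label[tr]; y_te <- meta$label[te]

      for (mo_name in names(model_specs)) {
        vals <- rep(NA_real_, 5)
        names(vals) <- c("auprc", "auroc", "brier_pos_x100", "brier_neg_x100",
                         "ace_percent")
        if (length(unique(y_tr)) == 2 && length(unique(y_te)) == 2) {
          probs <- train_predict(model_specs[[mo_name]],
                                 xm[tr, , drop = FALSE], y_tr,
                                 xm[te, , drop = FALSE],
                                 x_val = xm[va, , drop = FALSE],
                                 y_val = meta$label[va])
          probs <- pmin(pmax(as.numeric(probs), 0), 1)
          disc <- discrimination(y_te, probs)
          brier <- stratified_brier(y_te, probs)
          vals[] <- c(disc$auprc, disc$auroc, brier$brier_pos_x100,
                      brier$brier_neg_x100, ace(y_te, probs, n_bins))
        } else {
          warning(sprintf("fold %d (%s, %s): single-class split, cell undefined",
                          fold_i, fr_name, mo_name))
        }
        fold_rows[[length(fold_rows) + 1L]] <- data.table(
          framing = fr_name, model = mo_name, fold = fold_i,
          metric = names(vals), value = unname(vals))
      }
    }
  }

  folds_dt <- rbindlist(fold_rows)
  summary_dt <- if (nrow(folds_dt)) {
    folds_dt[, {
      v <- value[!is.na(value)]
      if (length(v) >= 2) {
        s <- summarize_folds(v)
        .(mean = s$mean, lo = s$lo, hi = s$hi)
      } else .(mean = NA_real_, lo = NA_real_, hi = NA_real_)
    }, by = .(framing, model, metric)]
  } else {
    data.table(framing = character(), model = character(), metric = character(),
               mean = numeric(), lo = numeric(), hi = numeric())
  }
  structure(list(folds = folds_dt, summary = summary_dt,
                 class_balance = rbindlist(bal_rows)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  cat("class balance per framing:\n")
  print(x$class_balance)
  cat("\nsummary (mean [95% CI] over folds):\n")
  s <- copy(x$summary)
  s[, text := sprintf("%.3f (%.3f-%.3f)", mean, lo, hi)]
  print(dcast(s, framing + model ~ metric, value.var = "text"))
  invisible(x)
}
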