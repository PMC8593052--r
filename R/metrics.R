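#' Stratified Brier score
#'
#' Mean squared error of the predicted probabilities computed separately
#' within each class, scaled by 100: `brier_pos_x100 = 100 * mean((1-p)^2)`
#' over positives and `brier_neg_x100 = 100 * mean(p^2)` over negatives.
#' The stratification makes calibration damage visible under class
#' imbalance, where the overall Brier score is dominated by the majority
#' class. An absent class yields `NA` for its component.
#'
#' @param labels 0/1 vector.
#' @param probs predicted probabilities in `[0, 1]`, same length.
#' @return list(`brier_pos_x100`, `brier_neg_x100`).
#' @export
stratified_brier <- function(labels, probs) {
  check_labels_probs(labels, probs)
  pos <- labels == 1
  list(
    brier_pos_x100 = if (any(pos)) 100 * mean((1 - probs[pos])^2) else NA_real_,
    brier_neg_x100 = if (any(!pos)) 100 * mean(probs[!pos]^2) else NA_real_
  )
}

check_labels_probs <- function(labels, probs) {
  if (!length(labels)) stop("empty input")
  stopifnot(length(labels) == length(probs))
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (any(probs < 0 | probs > 1 | !is.finite(probs))) {
    stop("probabilities must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Calibration bins
#'
#' Discretizes predicted probabilities into `n_bins` equal-width,
#' right-closed bins `(a, b]` over `[0, 1]` (probability 0 goes to the
#' first bin) and tabulates per-bin count, mean predicted probability and
#' observed positive fraction.
#'
#' @inheritParams stratified_brier
#' @param n_bins number of bins, default 10.
#' @return data.table (`bin`, `lo`, `hi`, `count`, `mean_pred`,
#'   `obs_frac`), one row per bin including empty ones.
#' @export
calibration_bins <- function(labels, probs, n_bins = 10) {
  check_labels_probs(labels, probs)
  stopifnot(n_bins >= 1)
  bin <- pmax(ceiling(probs * n_bins), 1L)
  dt <- data.table(bin = as.integer(bin), label = as.numeric(labels), prob = probs)
  agg <- dt[, .(count = .N, mean_pred = mean(prob), obs_frac = mean(label)),
            by = bin]
  full <- data.table(bin = seq_len(n_bins))
  out <- agg[full, on = "bin"]
  out[is.na(count), count := 0L]
  out[, `:=`(lo = (bin - 1) / n_bins, hi = bin / n_bins)]
  setcolorder(out, c("bin", "lo", "hi", "count", "mean_pred", "obs_frac"))
  setorder(out, bin)
  out[]
}

#' Average calibration error (ACE)
#'
#' Per non-empty calibration bin, the absolute difference between the
#' observed positive fraction and the mean predicted probability; these
#' differences are combined by an unweighted average over the non-empty
#' bins and expressed as a percentage. The equal weighting keeps the sparse
#' high-probability bins from being drowned out under class imbalance.
#'
#' @inheritParams calibration_bins
#' @return percent in `[0, 100]`.
#' @export
ace <- function(labels, probs, n_bins = 10) {
  bins <- calibration_bins(labels, probs, n_bins)
  occupied <- bins[count > 0]
  100 * mean(abs(occupied$obs_frac - occupied$mean_pred))
}

#' Discrimination metrics: AUROC and AUPRC
#'
#' AUROC by the rank statistic with midrank tie correction; AUPRC by step
#' integration of the precision--recall curve over the distinct score
#' thresholds (sum of precision times recall increment). Both classes must
#' be present.
#'
#' @inheritParams stratified_brier
#' @return list(`auroc`, `auprc`).
#' @export
discrimination <- function(labels, probs) {
  list(auroc = auroc(labels, probs), auprc = auprc(labels, probs))
}

#' @rdname discrimination
#' @export
auroc <- function(labels, probs) {
  check_labels_probs(labels, probs)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(probs)                              # midranks under ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @rdname discrimination
#' @export
auprc <- function(labels, probs) {
  check_labels_probs(labels, probs)
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels)) stop("both classes must be present")
  ord <- order(probs, decreasing = TRUE)
  lab <- labels[ord]; p <- probs[ord]
  ## group tied scores: one PR point per distinct threshold
  last_of_group <- c(p[-1] != p[-length(p)], TRUE)
  tp <- cumsum(lab)[last_of_group]
  n_at <- seq_along(lab)[last_of_group]
  precision <- tp / n_at
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Summarize per-fold metric values
#'
#' Mean with a t-based 95% confidence interval,
#' `mean +/- t(0.975, k-1) * sd / sqrt(k)`.
#'
#' @param values numeric vector of at least two per-fold values.
#' @return list(`mean`, `lo`, `hi`).
#' @export
summarize_folds <- function(values) {
  values <- values[!is.na(values)]
  k <- length(values)
  if (k < 2) stop("need at least two fold values")
  m <- mean(values)
  half <- qt(0.975, df = k - 1) * sd(values) / sqrt(k)
  list(mean = m, lo = m - half, hi = m + half)
}
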