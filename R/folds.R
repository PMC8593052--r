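#' Grouped five-fold cross-validation plan
#'
#' Patients are shuffled deterministically from the seed and divided into
#' `k` portions of ~20% each. Fold `i` holds out portion `i`, split in half
#' into validation and test (~10% each); the remaining portions train. All
#' samples of a patient inherit that patient's assignment, so no patient
#' ever contributes to two roles within a fold, and the test portions of
#' different folds are pairwise disjoint.
#'
#' @param patient_ids character vector (duplicates collapse).
#' @param k number of folds, default 5.
#' @param seed integer seed.
#' @return a `fold_plan`: data.table (`fold`, `patient_id`, `role` in
#'   train/validation/test) with attributes `k` and `seed`.
#' @export
split_folds <- function(patient_ids, k = 5, seed = 1L) {
  ids <- unique(as.character(patient_ids))
  n <- length(ids)
  if (n < 2 * k) {
    stop(sprintf("need at least %d patients for %d folds, got %d", 2 * k, k, n))
  }
  shuffled <- withr::with_seed(as.integer(seed), sample(ids))
  ## equal-size-as-possible contiguous portions of the shuffled order
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  portion <- rep(seq_len(k), times = sizes)

  plans <- lapply(seq_len(k), function(i) {
    held <- shuffled[portion == i]
    m <- length(held)
    val <- held[seq_len(m %/% 2)]
    test <- setdiff(held, val)
    data.table(
      fold = i,
      patient_id = shuffled,
      role = ifelse(shuffled %in% val, "validation",
                    ifelse(shuffled %in% test, "test", "train"))
    )
  })
  out <- rbindlist(plans)
  setattr(out, "class", c("fold_plan", class(out)))
  setattr(out, "k", k)
  setattr(out, "seed", as.integer(seed))
  out[]
}
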