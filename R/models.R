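#' Model specification for the benchmark
#'
#' The supported families and their backends: `extra_trees` and
#' `random_forest` (ranger, with `splitrule = "extratrees"` resp. `"gini"`),
#' `xgboost` (gradient boosting, native missing-value handling, optional
#' early stopping on a validation split), and `logistic_regression`
#' (`stats::glm`). Tree ensembles that cannot consume missing values
#' natively, and the logistic regression, receive train-fitted median
#' imputation; the logistic regression additionally gets train-fitted
#' standardization. Hyperparameters default to the backends' defaults plus
#' a fixed seed.
#'
#' @param family one of `"extra_trees"`, `"random_forest"`, `"xgboost"`,
#'   `"logistic_regression"`.
#' @param params named list of backend hyperparameter overrides.
#' @param seed integer seed for the backend RNG.
#' @return a `model_spec` list.
#' @export
model_spec <- function(family = c("extra_trees", "random_forest", "xgboost",
                                  "logistic_regression"),
                       params = list(), seed = 1L) {
  family <- tryCatch(match.arg(family), error = function(e) {
    stop("unsupported model family: ", family[1],
         " (supported: extra_trees, random_forest, xgboost, logistic_regression)",
         call. = FALSE)
  })
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "model_spec")
}

## train-fitted median imputation (all-missing columns fall back to 0)
fit_imputer <- function(x_train) {
  med <- apply(x_train, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  med
}

apply_imputer <- function(x, med) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- med[j]
  }
  x
}

#' Fit a model and predict event probabilities
#'
#' @param spec a [model_spec()].
#' @param x_train,x_eval numeric matrices with identical column names
#'   (`NA` = missing feature).
#' @param y_train 0/1 labels for the training rows.
#' @param x_val,y_val optional validation split, used for early stopping by
#'   the boosting family and ignored by the others.
#' @return numeric vector of probabilities for the rows of `x_eval`, with
#'   the fitted backend model attached as attribute `"model"`.
#' @export
train_predict <- function(spec, x_train, y_train, x_eval,
                          x_val = NULL, y_val = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  stopifnot(is.matrix(x_train), is.matrix(x_eval),
            identical(colnames(x_train), colnames(x_eval)))
  if (!all(y_train %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y_train)) < 2) {
    stop("degenerate training labels: only one class present")
  }

  probs <- switch(spec$family,
    extra_trees = ,
    random_forest = {
      med <- fit_imputer(x_train)
      xt <- apply_imputer(x_train, med)
      xe <- apply_imputer(x_eval, med)
      args <- list(
        x = as.data.frame(xt), y = factor(y_train, levels = c(0, 1)),
        probability = TRUE, num.trees = 300, seed = spec$seed,
        num.threads = 1, verbose = FALSE
      )
      if (spec$family == "extra_trees") {
        args <- c(args, list(splitrule = "extratrees", num.random.splits = 1,
                             replace = FALSE, sample.fraction = 1))
      }
      args <- utils::modifyList(args, spec$params)
      fit <- do.call(ranger::ranger, args)
      p <- predict(fit, data = as.data.frame(xe))$predictions[, "1"]
      attr(p, "model") <- fit
      p
    },
    xgboost = {
      params <- utils::modifyList(
        list(objective = "binary:logistic", eval_metric = "logloss",
             max_depth = 4, eta = 0.1, nthread = 1, seed = spec$seed,
             tree_method = "hist"),
        spec$params)
      dtrain <- xgboost::xgb.DMatrix(x_train, label = y_train)
      if (!is.null(x_val) && !is.null(y_val) && length(unique(y_val)) == 2) {
        dval <- xgboost::xgb.DMatrix(x_val, label = y_val)
        fit <- xgboost::xgb.train(params = params, data = dtrain, nrounds = 300,
                                  evals = list(validation = dval),
                                  early_stopping_rounds = 25, verbose = 0)
      } else {
        fit <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = 150, verbose = 0)
      }
      p <- predict(fit, xgboost::xgb.DMatrix(x_eval))
      attr(p, "model") <- fit
      p
    },
    logistic_regression = {
      med <- fit_imputer(x_train)
      xt <- apply_imputer(x_train, med)
      xe <- apply_imputer(x_eval, med)
      mu <- colMeans(xt)
      sdev <- apply(xt, 2, sd)
      sdev[sdev == 0 | !is.finite(sdev)] <- 1
      xt <- scale(xt, center = mu, scale = sdev)
      xe <- scale(xe, center = mu, scale = sdev)
      df_t <- as.data.frame(xt); df_e <- as.data.frame(xe)
      df_t$.y <- y_train
      fit <- suppressWarnings(glm(.y ~ ., data = df_t, family = binomial()))
      p <- suppressWarnings(
        as.numeric(predict(fit, newdata = df_e, type = "response")))
      attr(p, "model") <- fit
      p
    }
  )
  probs
}

#' Turn a feature set into a model matrix
#'
#' @param fs a `feature_set` from [featurize_samples()].
#' @return numeric matrix of the feature columns (rows in `fs$features`
#'   order).
#' @export
feature_matrix <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  ids <- fs$schema$id
  cols <- c(ids, paste0(ids, "_delta"))
  as.matrix(fs$features[, cols, with = FALSE])
}
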