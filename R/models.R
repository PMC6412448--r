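# Ensemble regression of blood pressure on waveform features.

#' Split a labelled dataset into train and test partitions
#'
#' Record mode assigns records to the training side uniformly at random,
#' with `round(ratio * n)` training records (round-half-even, as in base R's
#' `round`). Subject mode keeps all records of a subject on the same side,
#' accumulating shuffled subjects until the training fraction is reached —
#' use it to avoid leaking subject identity across the split.
#'
#' @param data data.frame with one row per record, containing a
#'   `subject_id` column when `mode = "subject"`.
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed.
#' @param mode `"record"` or `"subject"`.
#' @return `data` with an added `split` factor (`"train"`/`"test"`).
#' @export
split_dataset <- function(data, ratio = 0.8, seed = 1L,
                          mode = c("record", "subject")) {
  mode <- match.arg(mode)
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be in (0, 1)")
  n <- nrow(data)
  set.seed(seed)
  if (mode == "record") {
    n_train <- round(ratio * n)
    idx <- sample.int(n, n_train)
    split <- rep("test", n)
    split[idx] <- "train"
  } else {
    if (is.null(data$subject_id)) stop("subject mode requires a subject_id column")
    subjects <- sample(unique(data$subject_id))
    target <- ratio * n
    cum <- 0
    train_subj <- character(0)
    for (s in subjects) {
      if (cum >= target) break
      train_subj <- c(train_subj, s)
      cum <- cum + sum(data$subject_id == s)
    }
    split <- ifelse(data$subject_id %in% train_subj, "train", "test")
  }
  if (!all(c("train", "test") %in% split))
    stop("split left one side empty; adjust ratio")
  data$split <- factor(split, levels = c("train", "test"))
  data
}

#' Fit an ensemble blood-pressure regression model
#'
#' Fits one of three tree-ensemble regressors mapping waveform features to a
#' blood-pressure target: random forest regression (`"rfr"`,
#' \pkg{randomForest}), gradient-boosting regression (`"gbr"`,
#' \pkg{xgboost}, squared-error objective), or adaptive boosting regression
#' (`"abr"`, AdaBoost.R2 over depth-limited \pkg{rpart} trees). Fits are
#' deterministic given `seed`.
#'
#' @param formula model formula, e.g. `sbp_mmHg ~ .`; the response is the
#'   target pressure and all other numeric columns are features.
#' @param data training data.frame (typically the `"train"` rows of
#'   [split_dataset()] output).
#' @param algorithm `"rfr"`, `"gbr"` or `"abr"`.
#' @param n_estimators ensemble size (default 100).
#' @param max_depth tree depth limit: unlimited for `"rfr"` (the forest
#'   default), 3 for `"gbr"` and `"abr"`.
#' @param learning_rate shrinkage for `"gbr"` (default 0.1).
#' @param seed integer seed.
#' @return object of class `bp_model` with `predict`, `print` and `summary`
#'   methods.
#' @export
bp_model <- function(formula, data, algorithm = c("rfr", "gbr", "abr"),
                     n_estimators = 100L, max_depth = NULL,
                     learning_rate = 0.1, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (n_estimators < 1) stop("n_estimators must be >= 1")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- mf[, -1, drop = FALSE]
  # drop non-numeric bookkeeping columns picked up by a `~ .` formula
  x <- x[, vapply(x, is.numeric, TRUE), drop = FALSE]
  if (!ncol(x)) stop("no numeric feature columns in the model frame")
  if (!nrow(x)) stop("empty training partition")
  if (nrow(x) > 1 &&
      all(vapply(x, function(col) stats::var(col) == 0, TRUE)))
    stop("degenerate features: zero variance in all columns")
  target <- deparse(formula[[2]])
  set.seed(seed)
  fit <- switch(algorithm,
    rfr = randomForest::randomForest(
      x = x, y = y, ntree = n_estimators,
      maxnodes = if (is.null(max_depth)) NULL else 2L^max_depth),
    gbr = xgboost::xgb.train(
      params = list(max_depth = if (is.null(max_depth)) 3L else max_depth,
                    eta = learning_rate, objective = "reg:squarederror",
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
      nrounds = n_estimators, verbose = 0),
    abr = adaboost_r2_fit(x, y, n_estimators = n_estimators,
                          max_depth = if (is.null(max_depth)) 3L else max_depth,
                          seed = seed))
  structure(list(algorithm = algorithm, target = target, fit = fit,
                 feature_names = colnames(x), n_train = nrow(x),
                 n_estimators = n_estimators, learning_rate = learning_rate,
                 seed = seed, train_range = range(y), call = match.call()),
            class = "bp_model")
}

#' Predict blood pressure from waveform features
#'
#' @param object a [bp_model()] fit.
#' @param newdata data.frame containing every feature column used in
#'   training; a missing column raises an error naming it.
#' @param ... unused.
#' @return numeric vector of estimates in mmHg, one per row.
#' @export
predict.bp_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing_cols))
    stop("missing feature column: ", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  p <- switch(object$algorithm,
    rfr = as.numeric(predict(object$fit, x)),
    gbr = as.numeric(predict(object$fit, xgboost::xgb.DMatrix(as.matrix(x)))),
    abr = predict.adaboost_r2(object$fit, x))
  unname(p)
}

#' @export
print.bp_model <- function(x, ...) {
  alg <- c(rfr = "random forest", gbr = "gradient boosting",
           abr = "adaptive boosting (AdaBoost.R2)")[x$algorithm]
  cat(sprintf("bp_model: %s regression of %s on %d features\n",
              alg, x$target, length(x$feature_names)))
  cat(sprintf("  %d estimators, %d training records, target range %.1f-%.1f mmHg\n",
              x$n_estimators, x$n_train, x$train_range[1], x$train_range[2]))
  invisible(x)
}

#' @export
summary.bp_model <- function(object, ...) {
  imp <- switch(object$algorithm,
    rfr = {
      v <- randomForest::importance(object$fit)[, 1]
      sort(v / sum(v), decreasing = TRUE)
    },
    gbr = {
      tab <- xgboost::xgb.importance(model = object$fit)
      stats::setNames(tab$Gain, tab$Feature)
    },
    abr = {
      acc <- numeric(0)
      for (tr in object$fit$trees) {
        vi <- tr$variable.importance
        if (is.null(vi)) next
        for (nm in names(vi)) acc[nm] <- (if (nm %in% names(acc)) acc[nm] else 0) + vi[nm]
      }
      if (length(acc)) sort(acc / sum(acc), decreasing = TRUE) else acc
    })
  out <- list(model = object, importance = imp)
  class(out) <- "summary.bp_model"
  out
}

#' @export
print.summary.bp_model <- function(x, ...) {
  print(x$model)
  cat("relative feature importance:\n")
  print(round(x$importance, 3))
  invisible(x)
}
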