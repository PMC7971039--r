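#' Confusion counts at a probability threshold
#'
#' Predicted positive where `prob >= threshold`.
#'
#' @param y_true 0/1 labels.
#' @param y_prob probabilities in `[0, 1]` (hard labels also accepted).
#' @param threshold decision threshold (default 0.5).
#' @return a `confusion_counts` list: TP, FP, TN, FN.
#' @export
confusion <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) != length(y_prob)) {
    stop("length mismatch: ", length(y_true), " labels vs ",
         length(y_prob), " probabilities")
  }
  if (any(y_prob < 0 | y_prob > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(y_true %in% c(0, 1))) stop("labels must be 0/1")
  pred <- as.integer(y_prob >= threshold)
  structure(list(TP = sum(pred == 1 & y_true == 1),
                 FP = sum(pred == 1 & y_true == 0),
                 TN = sum(pred == 0 & y_true == 0),
                 FN = sum(pred == 0 & y_true == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NaN else num / den

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, F1, Matthews correlation coefficient,
#' specificity and sensitivity. F1 is the standard harmonic mean
#' `2 P S / (P + S)`; `as_printed = TRUE` instead returns
#' `P S / (P + S)` (half the standard value), matching a formulation
#' that omits the factor 2. Zero-denominator ratios are returned as NaN
#' and named in the `degenerate` attribute; an MCC with an empty
#' marginal is reported as 0 by the usual convention.
#'
#' @param counts a [confusion()] result (or list with TP/FP/TN/FN).
#' @param as_printed use the factor-2-free F1 variant (default FALSE).
#' @return a `metric_set` named list of the six values.
#' @export
metrics <- function(counts, as_printed = FALSE) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion table")
  precision <- safe_ratio(tp, tp + fp)
  sensitivity <- safe_ratio(tp, tp + fn)
  specificity <- safe_ratio(tn, tn + fp)
  f1 <- if (is.nan(precision) || is.nan(sensitivity) ||
            (precision + sensitivity) == 0) {
    NaN
  } else {
    (if (as_printed) 1 else 2) * precision * sensitivity /
      (precision + sensitivity)
  }
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  out <- list(accuracy = (tp + tn) / total, precision = precision, f1 = f1,
              mcc = mcc, specificity = specificity, sensitivity = sensitivity)
  degenerate <- names(out)[vapply(out, is.nan, logical(1))]
  if (length(degenerate)) {
    warning("degenerate metric(s) reported as NaN: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  structure(out, class = "metric_set", degenerate = degenerate)
}

#' @export
print.metric_set <- function(x, digits = 4, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%s=%.*f", names(v), digits, v), collapse = "  "), "\n")
  invisible(x)
}

#' ROC curve and area under it
#'
#' Threshold-sweep ROC over the distinct scores; area by the trapezoid
#' rule (equals the tie-corrected Mann-Whitney statistic).
#'
#' @param y_true 0/1 labels (both classes required).
#' @param y_prob scores (higher = more positive).
#' @return list with `curve` (data.frame fpr, tpr, threshold) and `auc`.
#' @export
roc_auc <- function(y_true, y_prob) {
  if (length(unique(y_true)) < 2) stop("both classes required for ROC")
  stopifnot(length(y_true) == length(y_prob))
  ord <- order(-y_prob)
  yt <- y_true[ord]; yp <- y_prob[ord]
  np <- sum(yt == 1); nn <- sum(yt == 0)
  tp <- cumsum(yt == 1); fp <- cumsum(yt == 0)
  last <- c(diff(yp) != 0, TRUE) # keep one point per distinct threshold
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  thr <- c(Inf, yp[last])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

stratified_folds <- function(y, folds = 5L, seed = 1L) {
  assign_fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      assign_fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign_fold
}

fit_predict_model <- function(model_spec, x_train, y_train, x_test, seed,
                              mlp = NULL) {
  if (is.list(model_spec) && !is.null(model_spec$fit)) {
    fit <- model_spec$fit(x_train, y_train)
    return(as.numeric(model_spec$predict(fit, x_test)))
  }
  if (identical(model_spec, "mlp")) {
    cfg <- if (is.null(mlp)) mlp_config(seed = seed) else mlp
    cfg$seed <- as.integer(seed)
    m <- build_mlp(cfg, ncol(x_train))
    m <- train(m, x_train, y_train)
    return(predict_proba(m, x_test))
  }
  baseline_fit_predict(model_spec, x_train, y_train, x_test, seed = seed)$prob
}

#' Stratified k-fold cross-validation of a configured pipeline
#'
#' Random stratified partition into `folds` folds; each fold is held out
#' once while balancing, feature ranking/selection and the model are
#' fitted on the remaining folds only (no leakage into the test fold),
#' then evaluated on it.
#'
#' @param fm a [feature_matrix()].
#' @param balance `"ncl"`, `"random"` or `"none"`.
#' @param ncl_k NCL neighbourhood size.
#' @param select_n number of top-ranked features to keep (NULL = all).
#' @param rf_trees,rf_depth forest parameters for the ranking.
#' @param model `"mlp"`, `"knn"`, `"rf"`, `"svm"`, `"snn"`, or a
#'   `list(fit = function(x, y), predict = function(fit, x))`.
#' @param mlp optional [mlp_config()] override for `model = "mlp"`.
#' @param folds number of folds (default 5).
#' @param seed RNG seed for fold assignment and model fitting.
#' @param threshold decision threshold for the confusion metrics.
#' @return a `cv_report`: per-fold `metric_set`s, ROC points and AUC,
#'   their means, and the fold assignment.
#' @export
cross_validate <- function(fm, balance = c("ncl", "random", "none"),
                           ncl_k = 3L, select_n = NULL, rf_trees = 300L,
                           rf_depth = 9L, model = "mlp", mlp = NULL,
                           folds = 5L, seed = 1L, threshold = 0.5) {
  balance <- match.arg(balance)
  stopifnot(inherits(fm, "feature_matrix"))
  if (min(table(fm$y)) < folds) {
    stop("need at least ", folds, " samples per class")
  }
  assign_fold <- stratified_folds(fm$y, folds, seed)
  fold_results <- lapply(seq_len(folds), function(f) {
    test_idx <- which(assign_fold == f)
    train_idx <- which(assign_fold != f)
    x_tr <- fm$x[train_idx, , drop = FALSE]
    y_tr <- fm$y[train_idx]
    bal <- switch(balance,
                  ncl = ncl_resample(x_tr, y_tr, k_neighbors = ncl_k),
                  random = random_undersample(x_tr, y_tr, seed = seed + f),
                  none = list(x = x_tr, y = y_tr))
    x_tr <- bal$x; y_tr <- bal$y
    x_te <- fm$x[test_idx, , drop = FALSE]
    if (!is.null(select_n)) {
      rk <- rank_features(x_tr, y_tr, n_trees = rf_trees, max_depth = rf_depth,
                          seed = seed + f)
      x_tr <- select_top(x_tr, rk, select_n)
      x_te <- x_te[, colnames(x_tr), drop = FALSE]
    }
    prob <- fit_predict_model(model, x_tr, y_tr, x_te, seed = seed + f,
                              mlp = mlp)
    y_te <- fm$y[test_idx]
    ms <- suppressWarnings(metrics(confusion(y_te, prob, threshold)))
    roc <- roc_auc(y_te, prob)
    list(metrics = ms, auc = roc$auc, roc = roc$curve,
         n_train = length(y_tr), n_test = length(y_te))
  })
  metric_names <- names(fold_results[[1]]$metrics)
  mean_metrics <- sapply(metric_names, function(m) {
    mean(vapply(fold_results, function(f) f$metrics[[m]], 0))
  })
  structure(list(folds = fold_results,
                 mean = as.list(mean_metrics),
                 mean_auc = mean(vapply(fold_results, `[[`, 0, "auc")),
                 fold_assignment = assign_fold,
                 n_folds = folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report:", x$n_folds, "folds (seed", x$seed, ")\n mean: ")
  v <- unlist(x$mean)
  cat(paste(sprintf("%s=%.4f", names(v), v), collapse = "  "),
      sprintf(" auc=%.4f\n", x$mean_auc))
  invisible(x)
}

#' Write a cv_report to JSON (plus optional per-fold ROC CSVs)
#'
#' @param report a [cross_validate()] result.
#' @param path output JSON file.
#' @param roc_dir optional directory for `roc_fold<i>.csv` files.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path, roc_dir = NULL) {
  obj <- list(
    n_folds = report$n_folds, seed = report$seed,
    mean = report$mean, mean_auc = report$mean_auc,
    folds = lapply(report$folds, function(f) {
      c(unclass(f$metrics), list(auc = f$auc, n_train = f$n_train,
                                 n_test = f$n_test))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(roc_dir)) {
    dir.create(roc_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(report$folds)) {
      write.csv(report$folds[[i]]$roc,
                file.path(roc_dir, sprintf("roc_fold%d.csv", i)),
                row.names = FALSE)
    }
  }
  invisible(path)
}
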