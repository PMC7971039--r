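#' Fit a random forest classifier
#'
#' Bagged CART trees on bootstrap samples, `mtry = floor(sqrt(p))`
#' features per split, Gini impurity. Deterministic under `seed`.
#'
#' @param x numeric matrix or [feature_matrix()].
#' @param y binary labels (ignored for a feature_matrix).
#' @param n_trees number of trees (default 300).
#' @param max_depth maximum tree depth (default 9).
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param min_node minimum samples per child node (default 1).
#' @param seed RNG seed.
#' @return an `aptaml_rf` model (trees, normalized importances, params).
#' @export
rf_fit <- function(x, y = NULL, n_trees = 300L, max_depth = 9L,
                   mtry = NULL, min_node = 1L, seed = 1L) {
  d <- as_xy(x, y)
  if (length(unique(d$y)) < 2L) stop("y must contain both classes")
  p <- ncol(d$x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  fit <- with_seed(seed, .rf_grow(d$x, d$y, as.integer(n_trees),
                                  as.integer(max_depth), as.integer(mtry),
                                  as.integer(min_node), TRUE))
  imp <- fit$importance
  names(imp) <- colnames(d$x)
  structure(list(trees = fit$trees, importance = imp,
                 features = colnames(d$x),
                 params = list(n_trees = n_trees, max_depth = max_depth,
                               mtry = mtry, min_node = min_node, seed = seed)),
            class = "aptaml_rf")
}

#' @export
print.aptaml_rf <- function(x, ...) {
  cat("aptaml_rf:", x$params$n_trees, "trees, max depth",
      x$params$max_depth, ",", length(x$features), "features\n")
  invisible(x)
}

#' @rdname predict_proba
#' @export
predict_proba.aptaml_rf <- function(model, x, ...) {
  x <- if (inherits(x, "feature_matrix")) x$x else as.matrix(x)
  check_schema(model$features, colnames(x))
  as.numeric(.rf_predict(model$trees, x[, model$features, drop = FALSE]))
}

#' Rank features by random-forest importance
#'
#' Grows a forest (defaults: 300 trees, depth 9) and ranks columns by
#' mean Gini impurity decrease, normalized to sum 1. Ties are broken by
#' column index. `importance = "permutation"` instead measures the mean
#' accuracy drop over `n_perm` column permutations.
#'
#' @inheritParams rf_fit
#' @param importance `"gini"` (default) or `"permutation"`.
#' @param n_perm permutations per feature for `"permutation"`.
#' @return a `feature_ranking`: data.frame (`rank`, `feature`,
#'   `importance`) sorted non-increasing, with the forest parameters
#'   attached.
#' @export
rank_features <- function(x, y = NULL, n_trees = 300L, max_depth = 9L,
                          seed = 1L, importance = c("gini", "permutation"),
                          n_perm = 5L) {
  importance <- match.arg(importance)
  d <- as_xy(x, y)
  fit <- rf_fit(d$x, d$y, n_trees = n_trees, max_depth = max_depth, seed = seed)
  imp <- if (importance == "gini") {
    v <- fit$importance
    if (sum(v) > 0) v / sum(v) else v
  } else {
    base_acc <- mean((predict_proba(fit, d$x) >= 0.5) == (d$y == 1))
    v <- with_seed(seed + 1L, vapply(seq_len(ncol(d$x)), function(j) {
      drops <- vapply(seq_len(n_perm), function(r) {
        xp <- d$x
        xp[, j] <- xp[sample(nrow(xp)), j]
        base_acc - mean((predict_proba(fit, xp) >= 0.5) == (d$y == 1))
      }, 0)
      mean(drops)
    }, 0))
    v <- pmax(v, 0)
    names(v) <- colnames(d$x)
    if (sum(v) > 0) v <- v / sum(v)
    v
  }
  ord <- order(-imp, seq_along(imp))
  out <- data.frame(rank = seq_along(imp), feature = names(imp)[ord],
                    importance = as.numeric(imp[ord]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("feature_ranking", "data.frame"),
            params = c(fit$params, importance = importance))
}

#' Keep the top-n ranked features
#'
#' Pure column filter: rows and retained values are untouched and the
#' original column order is preserved within the selection.
#'
#' @param x numeric matrix or [feature_matrix()].
#' @param ranking a [rank_features()] result.
#' @param n number of features to keep (default 193).
#' @return same type as `x`, restricted to the selected columns.
#' @export
select_top <- function(x, ranking, n = 193L) {
  fm <- inherits(x, "feature_matrix")
  m <- if (fm) x$x else as.matrix(x)
  if (n < 1 || n > ncol(m)) {
    stop("n = ", n, " outside 1..", ncol(m), " available features")
  }
  top <- ranking$feature[seq_len(n)]
  keep <- colnames(m)[colnames(m) %in% top]
  out <- m[, keep, drop = FALSE]
  if (fm) feature_matrix(out, x$y, x$pair_id) else out
}

#' Write a feature ranking as CSV
#' @param ranking a [rank_features()] result.
#' @param path output CSV (`rank`, `feature`, `importance`).
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  write.csv(as.data.frame(ranking), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
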