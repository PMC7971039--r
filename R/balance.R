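as_xy <- function(x, y) {
  if (inherits(x, "feature_matrix")) return(list(x = x$x, y = x$y, fm = x))
  x <- as.matrix(x)
  if (is.null(y) || length(y) != nrow(x)) {
    stop("y must have one label per row of x (", nrow(x), " rows, ",
         length(y), " labels)")
  }
  list(x = x, y = as.integer(y), fm = NULL)
}

# column z-scaling for neighbour distances; constant columns contribute 0
scale_cols <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev == 0] <- 1
  sweep(sweep(x, 2, mu), 2, sdev, "/")
}

# deterministic k nearest neighbours (self excluded); distance ties broken
# by lower sample index
knn_indices <- function(xs, k) {
  n <- nrow(xs)
  d <- as.matrix(dist(xs))
  diag(d) <- Inf
  t(vapply(seq_len(n), function(i) order(d[i, ], seq_len(n))[seq_len(k)],
           integer(k)))
}

#' Samples misclassified by their k nearest neighbours (ENN rule)
#'
#' Wilson's edited nearest neighbour vote: a sample is flagged when the
#' strict majority of its k nearest neighbours (excluding itself) carries
#' the opposite label -- for k = 3, when it differs from at least two of
#' its three nearest neighbours.
#'
#' @param x numeric matrix or [feature_matrix()].
#' @param y binary labels (ignored if `x` is a feature_matrix).
#' @param k number of neighbours (default 3).
#' @param scale_features z-scale columns before computing Euclidean
#'   distances (default TRUE).
#' @return logical mask over samples, TRUE where the vote disagrees.
#' @export
enn_misclassified <- function(x, y = NULL, k = 3L, scale_features = TRUE) {
  d <- as_xy(x, y)
  n <- nrow(d$x)
  if (n < k + 1L) stop("need at least k + 1 = ", k + 1, " samples, got ", n)
  xs <- if (scale_features) scale_cols(d$x) else d$x
  nb <- knn_indices(xs, k)
  vapply(seq_len(n), function(i) {
    disagree <- sum(d$y[nb[i, ]] != d$y[i])
    disagree * 2L > k
  }, logical(1))
}

#' Neighborhood Cleaning rule (NCL) undersampling
#'
#' Removes two sets of majority-class samples: A1, those flagged by the
#' ENN vote ([enn_misclassified()]); and A2, majority samples that sit
#' among the k nearest neighbours of a minority sample whose
#' neighbourhood vote misclassifies it. Minority samples are never
#' removed; surviving rows keep their original order. Deterministic.
#'
#' @inheritParams enn_misclassified
#' @param k_neighbors neighbourhood size (default 3).
#' @return a `feature_matrix` (if given one) or `list(x, y)` restricted to
#'   kept rows, with attribute `"removed"` holding the dropped row
#'   indices (and ids when available).
#' @export
ncl_resample <- function(x, y = NULL, k_neighbors = 3L, scale_features = TRUE) {
  d <- as_xy(x, y)
  n <- nrow(d$x)
  tab <- table(factor(d$y, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present")
  # smaller class is the minority; ties resolved to the positive class
  minority <- if (tab[["1"]] <= tab[["0"]]) 1L else 0L
  if (n < k_neighbors + 1L) {
    stop("need at least k + 1 = ", k_neighbors + 1, " samples, got ", n)
  }
  xs <- if (scale_features) scale_cols(d$x) else d$x
  nb <- knn_indices(xs, k_neighbors)
  flagged <- vapply(seq_len(n), function(i) {
    sum(d$y[nb[i, ]] != d$y[i]) * 2L > k_neighbors
  }, logical(1))
  is_minor <- d$y == minority
  a1 <- which(flagged & !is_minor)
  a2 <- unique(unlist(lapply(which(flagged & is_minor), function(i) {
    nbi <- nb[i, ]
    nbi[d$y[nbi] != minority]
  })))
  removed <- sort(unique(c(a1, a2)))
  keep <- setdiff(seq_len(n), removed)
  subset_xy(d, keep, removed)
}

subset_xy <- function(d, keep, removed) {
  if (!is.null(d$fm)) {
    out <- feature_matrix(d$fm$x[keep, , drop = FALSE], d$fm$y[keep],
                          d$fm$pair_id[keep])
    attr(out, "removed") <- d$fm$pair_id[removed]
    out
  } else {
    out <- list(x = d$x[keep, , drop = FALSE], y = d$y[keep])
    attr(out, "removed") <- removed
    out
  }
}

#' Random undersampling of the majority class
#'
#' Keeps every minority sample and a uniform random subset of the
#' majority class sized to the target majority:minority ratio.
#'
#' @inheritParams enn_misclassified
#' @param ratio target majority-to-minority ratio (default 1, i.e. 1:1).
#' @param seed integer seed; the selection is reproducible under it.
#' @return as [ncl_resample()]; surviving rows keep their original order.
#' @export
random_undersample <- function(x, y = NULL, ratio = 1, seed = 1L) {
  d <- as_xy(x, y)
  tab <- table(factor(d$y, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present")
  minority <- if (tab[["1"]] <= tab[["0"]]) 1L else 0L
  minor_idx <- which(d$y == minority)
  major_idx <- which(d$y != minority)
  target <- round(ratio * length(minor_idx))
  if (target < 1 || target > length(major_idx)) {
    stop("infeasible ratio ", ratio, ": would need ", target,
         " majority samples, have ", length(major_idx))
  }
  sel <- with_seed(seed, sample(major_idx, target))
  keep <- sort(c(minor_idx, sel))
  removed <- setdiff(seq_along(d$y), keep)
  subset_xy(d, keep, removed)
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
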