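test_that("confusion counts match hand tallies and validate input", {
  cc <- confusion(c(1, 1, 0, 0), c(0.9, 0.2, 0.8, 0.1))
  expect_identical(unclass(cc)[c("TP", "FN", "FP", "TN")],
                   list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  perfect <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_equal(perfect$FP + perfect$FN, 0)
  allpos <- confusion(c(1, 0, 0), c(0.9, 0.8, 0.7))
  expect_equal(allpos$TN + allpos$FN, 0)
  expect_error(confusion(c(1, 0), 0.5), "length mismatch")
  expect_error(confusion(c(1, 0), c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("metrics reproduce direct substitution into the definitions", {
  m <- metrics(list(TP = 1, FP = 1, TN = 1, FN = 1))
  expect_equal(unlist(m[c("accuracy", "precision", "f1", "specificity",
                          "sensitivity")]),
               c(accuracy = 0.5, precision = 0.5, f1 = 0.5,
                 specificity = 0.5, sensitivity = 0.5), tolerance = 1e-12)
  expect_equal(m$mcc, 0, tolerance = 1e-12)
  p <- metrics(list(TP = 7, FP = 0, TN = 5, FN = 0))
  expect_equal(unlist(unclass(p)), c(accuracy = 1, precision = 1, f1 = 1,
                                     mcc = 1, specificity = 1, sensitivity = 1))
  # a worked asymmetric table, computed by hand from the definitions
  h <- metrics(list(TP = 6, FP = 2, TN = 8, FN = 4))
  expect_equal(h$accuracy, 14 / 20, tolerance = 1e-12)
  expect_equal(h$precision, 6 / 8, tolerance = 1e-12)
  expect_equal(h$sensitivity, 6 / 10, tolerance = 1e-12)
  expect_equal(h$specificity, 8 / 10, tolerance = 1e-12)
  expect_equal(h$f1, 2 * (6 / 8) * (6 / 10) / (6 / 8 + 6 / 10), tolerance = 1e-12)
  expect_equal(h$mcc, (6 * 8 - 2 * 4) / sqrt(8 * 10 * 10 * 12), tolerance = 1e-12)
})

test_that("degenerate denominators flag NaN; the printed F1 variant halves", {
  expect_warning(m <- metrics(list(TP = 3, FP = 0, TN = 0, FN = 1)),
                 "specificity")
  expect_true(is.nan(m$specificity))
  expect_identical(attr(m, "degenerate"), "specificity")
  std <- metrics(list(TP = 6, FP = 2, TN = 8, FN = 4))
  half <- metrics(list(TP = 6, FP = 2, TN = 8, FN = 4), as_printed = TRUE)
  expect_equal(half$f1, std$f1 / 2)
  expect_error(metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)), "empty")
})

test_that("metrics from confusion equal metrics recomputed from raw vectors", {
  set.seed(31)
  for (rep in 1:5) {
    y <- rbinom(40, 1, 0.4)
    p <- runif(40)
    if (length(unique(y)) < 2) next
    m1 <- suppressWarnings(metrics(confusion(y, p, 0.35)))
    pred <- as.integer(p >= 0.35)
    m2 <- suppressWarnings(metrics(list(TP = sum(pred & y), FP = sum(pred & !y),
                                        TN = sum(!pred & !y), FN = sum(!pred & y))))
    expect_equal(m1, m2)
  }
})

test_that("roc_auc honours perfect separation, symmetry and the null", {
  y <- rep(c(1, 0), each = 10)
  s <- c(runif(10, 0.6, 1), runif(10, 0, 0.4))
  r <- roc_auc(y, s)
  expect_equal(r$auc, 1)
  expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
  set.seed(32)
  s2 <- runif(20)
  expect_equal(roc_auc(y, -s2)$auc, 1 - roc_auc(y, s2)$auc, tolerance = 1e-12)
  aucs <- vapply(1:5, function(seed) {
    set.seed(seed)
    yy <- rep(c(1, 0), each = 1000)
    roc_auc(yy, runif(2000))$auc
  }, 0)
  expect_true(all(abs(aucs - 0.5) < 0.05))
  expect_error(roc_auc(rep(1, 5), runif(5)), "both classes")
})

cv_fixture <- function(n = 60, seed = 41) {
  set.seed(seed)
  x <- matrix(rnorm(n * 6), n)
  colnames(x) <- paste0("f", 1:6)
  y <- as.integer(x[, 1] > 0)
  x[y == 1, 1] <- x[y == 1, 1] + 2
  feature_matrix(x, y)
}

test_that("cross_validate partitions samples once each, near-evenly", {
  fm <- cv_fixture()
  rpt <- cross_validate(fm, balance = "none", model = "rf", folds = 5, seed = 2)
  expect_length(rpt$fold_assignment, nrow(fm$x))
  expect_true(all(table(rpt$fold_assignment) %in% 11:13))
  # per class, fold sizes differ by at most 1
  for (cls in 0:1) {
    sizes <- table(rpt$fold_assignment[fm$y == cls])
    expect_lte(diff(range(sizes)), 1)
  }
  # mean equals the arithmetic mean of fold metrics
  for (nm in names(rpt$mean)) {
    expect_equal(rpt$mean[[nm]],
                 mean(vapply(rpt$folds, function(f) f$metrics[[nm]], 0)),
                 tolerance = 1e-12)
  }
  expect_equal(rpt$mean_auc, mean(vapply(rpt$folds, `[[`, 0, "auc")),
               tolerance = 1e-12)
  expect_error(cross_validate(cv_fixture(6), folds = 5), "per class")
})

test_that("balancing and selection never see the held-out fold", {
  fm <- cv_fixture(50, seed = 43)
  rownames(fm$x) <- fm$pair_id
  seen <- new.env()
  spy <- list(
    fit = function(x, y) {
      seen$train <- c(seen$train, list(rownames(x)))
      list(mu = mean(y))
    },
    predict = function(fit, x) {
      seen$test <- c(seen$test, list(rownames(x)))
      rep(fit$mu, nrow(x))
    })
  rpt <- cross_validate(fm, balance = "ncl", select_n = 3, model = spy,
                        folds = 5, seed = 3)
  expect_length(seen$train, 5)
  for (f in 1:5) {
    held_out <- fm$pair_id[rpt$fold_assignment == f]
    expect_identical(sort(seen$test[[f]]), sort(held_out))
    expect_length(intersect(seen$train[[f]], held_out), 0)
  }
})

test_that("cv reports serialize to JSON with per-fold blocks", {
  fm <- cv_fixture(40, seed = 44)
  rpt <- cross_validate(fm, balance = "none", model = "knn", folds = 4, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_cv_report(rpt, f)
  obj <- jsonlite::read_json(f)
  expect_equal(obj$n_folds, 4)
  expect_length(obj$folds, 4)
  expect_equal(obj$mean_auc, rpt$mean_auc, tolerance = 1e-9)
  expect_named(obj$folds[[1]], c("accuracy", "precision", "f1", "mcc",
                                 "specificity", "sensitivity", "auc",
                                 "n_train", "n_test"))
})
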