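test_that("mlp_config enforces the seven-layer contract", {
  expect_error(mlp_config(layer_sizes = c(8, 4, 1)), "exactly 7")
  expect_error(mlp_config(layer_sizes = c(64, 32, 16, 8, 4, 2, 3)), "width must be 1")
  expect_error(mlp_config(dropout_rate = 1), "dropout")
  expect_error(mlp_config(optimizer = "adam"), "unsupported optimizer")
  cfg <- mlp_config()
  expect_length(cfg$layer_sizes, 7)
  expect_equal(cfg$learning_rate, 0.00014)
  expect_equal(cfg$epochs, 260L)
  expect_equal(cfg$batch_size, 5000L)
})

test_that("build_mlp wires 7 dense layers ending in a sigmoid unit", {
  m <- build_mlp(mlp_config(), n_inputs = 12)
  expect_length(m$weights, 7)
  expect_identical(dim(m$weights[[1]]), c(12L, 256L))
  expect_identical(dim(m$weights[[7]]), c(8L, 1L))
  x <- matrix(rnorm(60), 5, 12)
  p <- aptaml:::mlp_forward(m, x)$out
  expect_true(all(p > 0 & p < 1))
  # ReLU spot values
  expect_equal(aptaml:::relu(c(-2, 3)), c(0, 3))
  expect_equal(aptaml:::sigmoid(0), 0.5)
})

test_that("training drives a separable toy set to >= 0.99 accuracy", {
  toy <- toy_separable(200)
  cfg <- mlp_config(epochs = 500, seed = 3)
  m <- train(build_mlp(cfg, ncol(toy$x)), toy$x, toy$y)
  expect_equal(nrow(m$history), 500)
  expect_gte(tail(m$history$accuracy, 1), 0.99)
  expect_lte(tail(m$history$loss, 1), m$history$loss[1])
  # cross-entropy vanishes at perfect prediction
  expect_equal(aptaml:::bce(c(0, 1), c(1e-15, 1 - 1e-15)), 0, tolerance = 1e-9)
})

test_that("training is deterministic without dropout and inference always is", {
  toy <- toy_separable(80, seed = 4)
  cfg <- mlp_config(epochs = 30, dropout_rate = 0, seed = 11)
  m1 <- train(build_mlp(cfg, ncol(toy$x)), toy$x, toy$y)
  m2 <- train(build_mlp(cfg, ncol(toy$x)), toy$x, toy$y)
  expect_identical(m1$history, m2$history)
  p <- predict_proba(m1, toy$x)
  expect_identical(p, predict_proba(m1, toy$x))
  # duplicated input row gets the identical probability
  xdup <- toy$x[c(1, 1), , drop = FALSE]
  pd <- predict_proba(m1, xdup)
  expect_identical(pd[1], pd[2])
})

test_that("serialization round-trip preserves predictions", {
  toy <- toy_separable(60, seed = 5)
  m <- train(build_mlp(mlp_config(epochs = 20, seed = 2), ncol(toy$x)),
             toy$x, toy$y)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(predict_proba(m2, toy$x), predict_proba(m, toy$x),
               tolerance = 1e-7)
})

test_that("schema mismatches and non-finite inputs are rejected", {
  toy <- toy_separable(60, seed = 6)
  m <- train(build_mlp(mlp_config(epochs = 5, seed = 1), ncol(toy$x)),
             toy$x, toy$y)
  bad <- toy$x
  colnames(bad) <- c(paste0("f", 1:4), "other")
  expect_error(predict_proba(m, bad), "missing.*f5.*extra.*other")
  xna <- toy$x
  xna[1, 1] <- NA
  expect_error(train(build_mlp(mlp_config(epochs = 5, seed = 1), 5), xna, toy$y),
               "non-finite")
})

test_that("all four baselines clear 0.9 accuracy on the separable toy", {
  tr <- toy_separable(200, seed = 7)
  te <- toy_separable(100, seed = 8)
  for (b in c("knn", "rf", "svm", "snn")) {
    r <- baseline_fit_predict(b, tr$x, tr$y, te$x, seed = 1)
    expect_gte(mean(r$label == te$y), 0.9)
    expect_true(all(r$prob >= 0 & r$prob <= 1))
  }
  expect_error(baseline_fit_predict("cnn", tr$x, tr$y, te$x), "unknown baseline")
})

test_that("knn follows its duplicate-dominated neighbourhood", {
  # 4 duplicates of the query at label 1, k = 5: majority must be 1
  x_train <- rbind(matrix(0, 4, 2), matrix(5, 10, 2))
  y_train <- rep(c(1L, 0L), c(4, 10))
  r <- baseline_fit_predict("knn", x_train, y_train, matrix(0, 1, 2))
  expect_identical(r$label, 1L)
})
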