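#' Configuration for the seven-layer MLP
#'
#' Exactly 7 fully connected layers ending in a single sigmoid unit;
#' hidden activations are ReLU with (inverted) dropout after every
#' hidden layer. Layer widths are configurable (only the depth is
#' fixed); the default taper is 256-128-64-32-16-8-1. The effective
#' batch is `min(batch_size, n)`, so the large default batch size makes
#' desk-scale training full-batch.
#'
#' @param layer_sizes 7 widths, last must be 1.
#' @param dropout_rate dropout fraction in `[0, 1)` (default 0.3).
#' @param learning_rate RMSprop step size (default 0.00014).
#' @param batch_size minibatch size (default 5000, capped at n).
#' @param epochs training epochs (default 260).
#' @param optimizer only `"rmsprop"` is implemented.
#' @param seed RNG seed for init, shuffling and dropout.
#' @return an `mlp_config` list.
#' @export
mlp_config <- function(layer_sizes = c(256L, 128L, 64L, 32L, 16L, 8L, 1L),
                       dropout_rate = 0.3, learning_rate = 0.00014,
                       batch_size = 5000L, epochs = 260L,
                       optimizer = "rmsprop", seed = 1L) {
  if (length(layer_sizes) != 7L) {
    stop("layer_sizes must have exactly 7 entries, got ", length(layer_sizes))
  }
  if (layer_sizes[7] != 1L) stop("final layer width must be 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (!identical(optimizer, "rmsprop")) stop("unsupported optimizer: ", optimizer)
  structure(list(layer_sizes = as.integer(layer_sizes),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "mlp_config")
}

relu <- function(x) (x + abs(x)) / 2
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Build an untrained seven-layer MLP
#'
#' He-normal weight initialization, zero biases, seeded.
#'
#' @param config an [mlp_config()].
#' @param n_inputs number of input features.
#' @return an `aptanet_mlp` model object (untrained).
#' @export
build_mlp <- function(config = mlp_config(), n_inputs) {
  stopifnot(inherits(config, "mlp_config"), n_inputs >= 1)
  dims <- c(n_inputs, config$layer_sizes)
  weights <- with_seed(config$seed, lapply(seq_len(7L), function(l) {
    matrix(rnorm(dims[l] * dims[l + 1]) * sqrt(2 / dims[l]),
           dims[l], dims[l + 1])
  }))
  biases <- lapply(seq_len(7L), function(l) numeric(dims[l + 1]))
  structure(list(weights = weights, biases = biases, config = config,
                 n_inputs = n_inputs, features = NULL, center = NULL,
                 scale = NULL, history = NULL, trained = FALSE),
            class = "aptanet_mlp")
}

#' @export
print.aptanet_mlp <- function(x, ...) {
  cat("aptanet_mlp: 7 dense layers (",
      paste(x$config$layer_sizes, collapse = "-"), "), ", x$n_inputs,
      " inputs, ", if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

mlp_forward <- function(model, x, dropout = 0, masks = NULL) {
  a <- x
  acts <- vector("list", 7L)
  for (l in 1:7) {
    z <- sweep(a %*% model$weights[[l]], 2, model$biases[[l]], "+")
    if (l < 7) {
      a <- relu(z)
      if (dropout > 0) a <- a * masks[[l]]
    } else {
      a <- sigmoid(z)
    }
    acts[[l]] <- a
  }
  list(out = as.numeric(acts[[7]]), acts = acts)
}

bce <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a model
#' @param model a model object (e.g. from [build_mlp()]).
#' @param ... passed to methods.
#' @export
train <- function(model, ...) UseMethod("train")

#' Train the MLP under binary cross-entropy with RMSprop
#'
#' Inputs are z-scaled with statistics fitted on the training data (kept
#' in the model). Minibatches of `min(batch_size, n)` rows, reshuffled
#' each epoch; inverted dropout after every hidden layer; per-epoch
#' full-set loss and accuracy recorded in `model$history`. Deterministic
#' under the config seed.
#'
#' @param model an `aptanet_mlp` from [build_mlp()].
#' @param x training features (matrix or [feature_matrix()]).
#' @param y binary labels (ignored for a feature_matrix).
#' @param epochs optional override of the config value.
#' @param ... unused.
#' @return the trained model, with `history` (epoch, loss, accuracy).
#' @export
train.aptanet_mlp <- function(model, x, y = NULL, epochs = NULL, ...) {
  d <- as_xy(x, y)
  if (any(!is.finite(d$x))) stop("non-finite training inputs")
  cfg <- model$config
  if (!is.null(epochs)) cfg$epochs <- as.integer(epochs)
  n <- nrow(d$x)
  stopifnot(ncol(d$x) == model$n_inputs)
  model$features <- colnames(d$x)
  model$center <- colMeans(d$x)
  sdev <- apply(d$x, 2, sd)
  sdev[sdev == 0] <- 1
  model$scale <- sdev
  xs <- sweep(sweep(d$x, 2, model$center), 2, model$scale, "/")
  yv <- as.numeric(d$y)
  batch <- min(cfg$batch_size, n)
  rho <- 0.9; eps <- 1e-7
  vW <- lapply(model$weights, function(w) w * 0)
  vb <- lapply(model$biases, function(b) b * 0)
  hist_loss <- hist_acc <- numeric(cfg$epochs)
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch)) {
        rows <- ord[start:min(start + batch - 1L, n)]
        xb <- xs[rows, , drop = FALSE]
        yb <- yv[rows]
        m <- length(rows)
        masks <- NULL
        if (cfg$dropout_rate > 0) {
          masks <- lapply(1:6, function(l) {
            keep <- matrix(runif(m * cfg$layer_sizes[l]) >= cfg$dropout_rate,
                           m, cfg$layer_sizes[l])
            keep / (1 - cfg$dropout_rate)
          })
        }
        fw <- mlp_forward(model, xb, cfg$dropout_rate, masks)
        # backprop: sigmoid + BCE gives delta = a - y at the output
        delta <- matrix(fw$acts[[7]] - yb, m, 1) / m
        for (l in 7:1) {
          a_prev <- if (l == 1) xb else fw$acts[[l - 1]]
          gW <- crossprod(a_prev, delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- delta %*% t(model$weights[[l]])
            delta <- delta * (fw$acts[[l - 1]] > 0)
            if (cfg$dropout_rate > 0) delta <- delta * masks[[l - 1]]
          }
          vW[[l]] <- rho * vW[[l]] + (1 - rho) * gW^2
          vb[[l]] <- rho * vb[[l]] + (1 - rho) * gb^2
          model$weights[[l]] <- model$weights[[l]] -
            cfg$learning_rate * gW / (sqrt(vW[[l]]) + eps)
          model$biases[[l]] <- model$biases[[l]] -
            cfg$learning_rate * gb / (sqrt(vb[[l]]) + eps)
        }
      }
      p <- mlp_forward(model, xs)$out
      hist_loss[ep] <- bce(yv, p)
      hist_acc[ep] <- mean((p >= 0.5) == (yv == 1))
    }
  })
  model$history <- data.frame(epoch = seq_len(cfg$epochs), loss = hist_loss,
                              accuracy = hist_acc)
  model$config <- cfg
  model$trained <- TRUE
  model
}

check_schema <- function(expected, got) {
  if (is.null(expected) || is.null(got)) return(invisible(TRUE))
  missing <- setdiff(expected, got)
  extra <- setdiff(got, expected)
  if (length(missing) || length(extra)) {
    stop("feature schema mismatch; missing: [",
         paste(head(missing, 5), collapse = ", "), if (length(missing) > 5) ", ..." else "",
         "], extra: [", paste(head(extra, 5), collapse = ", "),
         if (length(extra) > 5) ", ..." else "", "]")
  }
  invisible(TRUE)
}

#' Predict class-1 probabilities
#'
#' @param model a trained model (`aptanet_mlp`, `aptaml_rf`, ...).
#' @param x features with the same column schema as at training time
#'   (mismatch raises an error listing missing/extra columns).
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, x, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.aptanet_mlp <- function(model, x, ...) {
  x <- if (inherits(x, "feature_matrix")) x$x else as.matrix(x)
  check_schema(model$features, colnames(x))
  if (!is.null(model$features)) x <- x[, model$features, drop = FALSE]
  if (!is.null(model$center)) {
    x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  }
  mlp_forward(model, x)$out
}

#' Save / load a trained model (single-file serialization)
#'
#' The configuration, scaling statistics and training history travel
#' with the weights; a round-trip preserves predictions.
#'
#' @param model a model object.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

# ---- baseline classifiers ------------------------------------------------

# linear SVM (C = 1) by L-BFGS on the L2-regularized squared-hinge
# objective; decision values mapped through a logistic for probabilities
svm_linear_fit <- function(x, y, C = 1, seed = 1L) {
  ys <- ifelse(y == 1, 1, -1)
  mu <- colMeans(x); sdev <- apply(x, 2, sd); sdev[sdev == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  p <- ncol(xs)
  obj <- function(par) {
    w <- par[1:p]; b <- par[p + 1]
    m <- pmax(0, 1 - ys * (xs %*% w + b))
    0.5 * sum(w^2) + C * sum(m^2)
  }
  grad <- function(par) {
    w <- par[1:p]; b <- par[p + 1]
    m <- pmax(0, 1 - ys * (as.numeric(xs %*% w) + b))
    gw <- w - 2 * C * as.numeric(crossprod(xs, ys * m))
    gb <- -2 * C * sum(ys * m)
    c(gw, gb)
  }
  init <- with_seed(seed, rnorm(p + 1) * 1e-3)
  fit <- optim(init, obj, grad, method = "L-BFGS-B",
               control = list(maxit = 500))
  list(w = fit$par[1:p], b = fit$par[p + 1], center = mu, scale = sdev)
}

svm_linear_decision <- function(fit, x) {
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  as.numeric(xs %*% fit$w + fit$b)
}

# small fully connected net (hidden widths e.g. c(3, 2)), ReLU hidden,
# sigmoid output, BCE + alpha/2 * ||W||^2, trained full-batch by BFGS
snn_fit <- function(x, y, hidden = c(3L, 2L), alpha = 1e-4, seed = 1L,
                    maxit = 500L) {
  mu <- colMeans(x); sdev <- apply(x, 2, sd); sdev[sdev == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  dims <- c(ncol(xs), hidden, 1L)
  L <- length(dims) - 1L
  shapes <- lapply(seq_len(L), function(l) c(dims[l], dims[l + 1]))
  nw <- sum(vapply(shapes, prod, 0)) + sum(dims[-1])
  unpack <- function(par) {
    Ws <- vector("list", L); bs <- vector("list", L); off <- 0L
    for (l in seq_len(L)) {
      k <- shapes[[l]][1] * shapes[[l]][2]
      Ws[[l]] <- matrix(par[(off + 1):(off + k)], shapes[[l]][1], shapes[[l]][2])
      off <- off + k
    }
    for (l in seq_len(L)) {
      k <- dims[l + 1]
      bs[[l]] <- par[(off + 1):(off + k)]
      off <- off + k
    }
    list(W = Ws, b = bs)
  }
  n <- nrow(xs)
  fwd <- function(pr) {
    a <- xs; acts <- vector("list", L)
    for (l in seq_len(L)) {
      z <- sweep(a %*% pr$W[[l]], 2, pr$b[[l]], "+")
      a <- if (l < L) relu(z) else sigmoid(z)
      acts[[l]] <- a
    }
    acts
  }
  obj <- function(par) {
    pr <- unpack(par)
    p <- as.numeric(fwd(pr)[[L]])
    bce(y, p) + alpha / 2 * sum(vapply(pr$W, function(w) sum(w^2), 0))
  }
  grad <- function(par) {
    pr <- unpack(par)
    acts <- fwd(pr)
    delta <- matrix(as.numeric(acts[[L]]) - y, n, 1) / n
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in L:1) {
      a_prev <- if (l == 1) xs else acts[[l - 1]]
      gW[[l]] <- crossprod(a_prev, delta) + alpha * pr$W[[l]]
      gb[[l]] <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(pr$W[[l]])) * (acts[[l - 1]] > 0)
    }
    c(unlist(gW), unlist(gb))
  }
  init <- with_seed(seed, rnorm(nw) * 0.5)
  fit <- optim(init, obj, grad, method = "BFGS", control = list(maxit = maxit))
  list(par = unpack(fit$par), dims = dims, center = mu, scale = sdev, L = L)
}

snn_predict <- function(fit, x) {
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  a <- xs
  for (l in seq_len(fit$L)) {
    z <- sweep(a %*% fit$par$W[[l]], 2, fit$par$b[[l]], "+")
    a <- if (l < fit$L) relu(z) else sigmoid(z)
  }
  as.numeric(a)
}

#' Fit-and-predict one of the comparison classifiers
#'
#' The four reference baselines with their conventional hyperparameters:
#' `knn` (k = 5, Euclidean), `rf` (10 trees, depth 3), `svm` (linear
#' kernel, C = 1; trained here on the smooth squared-hinge objective),
#' `snn` (hidden widths 3 and 2, full-batch quasi-Newton, L2 alpha
#' 0.0001).
#'
#' @param name one of `"knn"`, `"rf"`, `"svm"`, `"snn"`.
#' @param x_train,y_train training data.
#' @param x_test rows to predict.
#' @param seed RNG seed.
#' @return list with `prob` (class-1 probabilities) and `label`
#'   (0/1 at threshold 0.5).
#' @export
baseline_fit_predict <- function(name, x_train, y_train, x_test, seed = 1L) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  prob <- switch(
    name,
    knn = {
      pr <- FNN::knn(x_train, x_test, factor(y_train, levels = c(0, 1)),
                     k = 5, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    rf = {
      fit <- rf_fit(x_train, y_train, n_trees = 10L, max_depth = 3L, seed = seed)
      predict_proba(fit, x_test)
    },
    svm = {
      fit <- svm_linear_fit(x_train, y_train, C = 1, seed = seed)
      sigmoid(svm_linear_decision(fit, x_test))
    },
    snn = {
      fit <- snn_fit(x_train, y_train, hidden = c(3L, 2L), alpha = 1e-4,
                     seed = seed)
      snn_predict(fit, x_test)
    },
    stop("unknown baseline classifier: ", name)
  )
  list(prob = as.numeric(prob), label = as.integer(prob >= 0.5))
}
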