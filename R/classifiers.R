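#' Model configuration
#'
#' Describes one of the six classifier families and its input kind.
#' The pairing is fixed: `svm`, `xgb`, `lgbm` and `ann` consume the
#' 14-feature table, `cnn1d` consumes zero-padded raw audio, `cnn2d`
#' consumes 40x40 spectral crops.
#'
#' @param family One of `"svm"`, `"xgb"`, `"lgbm"`, `"ann"`, `"cnn1d"`,
#'   `"cnn2d"`.
#' @param hyper Named list of hyperparameter overrides (epochs,
#'   batch_size, lr, nrounds, max_depth, cost, aggregation, ...).
#' @param seed Integer seed used for initialization and training.
#' @return An object of class `model_config`.
#' @export
model_config <- function(family = c("svm", "xgb", "lgbm", "ann",
                                    "cnn1d", "cnn2d"),
                         hyper = list(), seed = 1L) {
  family <- match.arg(family)
  input_kind <- switch(family,
                       svm = , xgb = , lgbm = , ann = "features",
                       cnn1d = "raw1d", cnn2d = "image")
  structure(list(family = family, input_kind = input_kind,
                 hyper = hyper, seed = as.integer(seed)),
            class = "model_config")
}

default_hyper <- function(family) {
  switch(family,
         svm = list(kernel = "radial", cost = 1),
         xgb = list(nrounds = 200L, max_depth = 4L, eta = 0.1),
         lgbm = list(nrounds = 200L, max_leaves = 16L, eta = 0.1),
         ann = list(hidden = c(32L, 16L), epochs = 60L, batch_size = 8L,
                    lr = 1e-3),
         cnn1d = list(input_len = 98304L, epochs = 16L, batch_size = 8L,
                      lr = 1e-3),
         cnn2d = list(epochs = 30L, batch_size = 16L, lr = 1e-3,
                      dropout = 0.3, aggregation = "mean"))
}

resolve_hyper <- function(config) {
  hp <- default_hyper(config$family)
  hp[names(config$hyper)] <- config$hyper
  hp
}

# 1D-CNN: six convolution blocks (conv->BN->ReLU, the first five each
# followed by max pooling 8,8,8,8,4; the sixth keeps 256 channels with
# no pool) then dense 1536 -> 100 -> 50 -> 2. For the 98,304-sample
# input the pooling product 16,384 leaves 6 time steps x 256 channels
# = 1536 flattened features.
build_cnn1d_layers <- function(input_len) {
  chans <- c(16L, 32L, 64L, 128L, 256L)
  pools <- c(8L, 8L, 8L, 8L, 4L)
  layers <- list()
  c_in <- 1L
  len <- input_len
  for (i in seq_along(chans)) {
    layers <- c(layers, list(nn_conv1d(c_in, chans[i]), nn_bn(chans[i]),
                             nn_relu(), nn_pool1d(pools[i])))
    if (len %% pools[i] != 0L) {
      stop("build_model: input_len not divisible by the pooling chain")
    }
    len <- len %/% pools[i]
    c_in <- chans[i]
  }
  layers <- c(layers, list(nn_conv1d(256L, 256L), nn_bn(256L), nn_relu()))
  flat <- len * 256L
  c(layers, list(nn_flatten(), nn_dense(flat, 100L), nn_relu(),
                 nn_dense(100L, 50L), nn_relu(), nn_dense(50L, 2L)))
}

# 2D-CNN on 40x40 single-channel crops: three 3x3 convolution blocks
# (64, 64, 128 channels, ReLU), one conservative 2x2 max pool after the
# last block, then dense 500 -> 50 -> 2 with dropout 0.3 after each of
# the first two dense layers.
build_cnn2d_layers <- function(dropout = 0.3) {
  set_hw <- function(l, h, w) { l$h <- h; l$w <- w; l }
  layers <- list(
    set_hw(nn_conv2d(1L, 64L), 40L, 40L), nn_relu(),
    set_hw(nn_conv2d(64L, 64L), 40L, 40L), nn_relu(),
    set_hw(nn_conv2d(64L, 128L), 40L, 40L), nn_relu(),
    set_hw(nn_pool2d(2L), 40L, 40L),
    nn_flatten(),
    nn_dense(20L * 20L * 128L, 500L), nn_relu(), nn_dropout(dropout),
    nn_dense(500L, 50L), nn_relu(), nn_dropout(dropout),
    nn_dense(50L, 2L))
  layers
}

# layer indices of the parameterized layers in build_cnn1d_layers()
cnn1d_conv_idx <- function() c(1L, 5L, 9L, 13L, 17L, 21L)
cnn1d_dense_idx <- function() c(25L, 27L, 29L)

# R layer list -> flat weight list consumed by the C++ trainer
r_net_to_cpp_weights <- function(net) {
  ci <- cnn1d_conv_idx()
  list(conv_w = lapply(ci, function(i) net$layers[[i]]$W),
       conv_b = lapply(ci, function(i) net$layers[[i]]$b),
       bn_gamma = lapply(ci + 1L, function(i) net$layers[[i]]$gamma),
       bn_beta = lapply(ci + 1L, function(i) net$layers[[i]]$beta),
       bn_rmean = lapply(ci + 1L, function(i) net$layers[[i]]$run_mean),
       bn_rvar = lapply(ci + 1L, function(i) net$layers[[i]]$run_var),
       dense_w = lapply(cnn1d_dense_idx(), function(i) net$layers[[i]]$W),
       dense_b = lapply(cnn1d_dense_idx(), function(i) net$layers[[i]]$b))
}

# write trained C++ weights back into the R layer list
cpp_weights_to_r_net <- function(net, w) {
  ci <- cnn1d_conv_idx()
  for (j in seq_along(ci)) {
    net$layers[[ci[j]]]$W <- w$conv_w[[j]]
    net$layers[[ci[j]]]$b <- as.vector(w$conv_b[[j]])
    net$layers[[ci[j] + 1L]]$gamma <- as.vector(w$bn_gamma[[j]])
    net$layers[[ci[j] + 1L]]$beta <- as.vector(w$bn_beta[[j]])
    net$layers[[ci[j] + 1L]]$run_mean <- as.vector(w$bn_rmean[[j]])
    net$layers[[ci[j] + 1L]]$run_var <- as.vector(w$bn_rvar[[j]])
  }
  di <- cnn1d_dense_idx()
  for (j in seq_along(di)) {
    net$layers[[di[j]]]$W <- w$dense_w[[j]]
    net$layers[[di[j]]]$b <- as.vector(w$dense_b[[j]])
  }
  net
}

#' Build an untrained model
#'
#' Instantiates the architecture for a [model_config()]. Network
#' families are initialized (Glorot-uniform) under the config seed, so
#' two builds with the same seed have identical initial parameters.
#'
#' @param config A [model_config()].
#' @return An object of class `voxpath_model` (untrained).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  hp <- resolve_hyper(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  net <- switch(config$family,
                ann = {
                  sizes <- c(14L, hp$hidden, 2L)
                  layers <- list()
                  for (i in seq_len(length(sizes) - 1L)) {
                    layers <- c(layers, list(nn_dense(sizes[i], sizes[i + 1L])))
                    if (i < length(sizes) - 1L) layers <- c(layers, list(nn_relu()))
                  }
                  list(layers = layers)
                },
                cnn1d = list(layers = build_cnn1d_layers(hp$input_len)),
                cnn2d = list(layers = build_cnn2d_layers(hp$dropout)),
                NULL)
  structure(list(config = config, hyper = hp, net = net, fit = NULL,
                 classes = c("normal", "pathological"),
                 feature_names = NULL, scaling = NULL, trained = FALSE),
            class = "voxpath_model")
}

#' @export
print.voxpath_model <- function(x, ...) {
  cat(sprintf("<voxpath_model:%s> input=%s %s\n", x$config$family,
              x$config$input_kind,
              if (x$trained) "(trained)" else "(untrained)"))
  invisible(x)
}

as_label_int <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (!all(labels %in% c("normal", "pathological"))) {
    stop("labels must be 'normal' or 'pathological'")
  }
  ifelse(labels == "pathological", 2L, 1L)  # 1 = normal, 2 = pathological
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2L) {
    stop("train_model: training set contains a single class")
  }
  if (min(table(y)) < 2L) {
    stop("train_model: need at least 2 examples per class")
  }
}

#' Train a model
#'
#' Fits a [build_model()] output on training data of the matching input
#' kind. Feature-table families take a numeric matrix or data.frame of
#' the 14 acoustic features; `cnn1d` takes a list of equal-length
#' zero-padded [voice_signal()]s (or bare numeric vectors); `cnn2d`
#' takes a list of 40x40 matrices (crops).
#'
#' @param model An untrained `voxpath_model`.
#' @param x Inputs, see above.
#' @param labels Character/factor labels, `"normal"`/`"pathological"`.
#' @param ... Hyperparameter overrides for this call (e.g. `epochs`).
#' @return The trained `voxpath_model`.
#' @export
train_model <- function(model, x, labels, ...) {
  stopifnot(inherits(model, "voxpath_model"))
  y <- as_label_int(labels)
  check_two_classes(y)
  hp <- model$hyper
  dots <- list(...)
  hp[names(dots)] <- dots
  fam <- model$config$family
  seed <- model$config$seed

  if (model$config$input_kind == "features") {
    x <- as.matrix(as.data.frame(x))
    storage.mode(x) <- "double"
    model$feature_names <- colnames(x)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  if (fam == "svm") {
    yf <- factor(c("normal", "pathological")[y],
                 levels = c("normal", "pathological"))
    model$fit <- e1071::svm(x, yf, kernel = hp$kernel, cost = hp$cost,
                            probability = TRUE, scale = TRUE)
  } else if (fam %in% c("xgb", "lgbm")) {
    params <- list(objective = "binary:logistic", max_depth = hp$max_depth,
                   eta = hp$eta, nthread = 1L)
    if (fam == "lgbm") {
      # leaf-wise histogram growth, the strategy that defines LightGBM
      params$tree_method <- "hist"
      params$grow_policy <- "lossguide"
      params$max_depth <- 0L
      params$max_leaves <- hp$max_leaves
    }
    dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y == 2L))
    model$fit <- xgboost::xgb.train(params = params, data = dtrain,
                                    nrounds = hp$nrounds, verbose = 0)
  } else if (fam == "ann") {
    mu <- colMeans(x)
    sdv <- apply(x, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    model$scaling <- list(mu = mu, sd = sdv)
    xs <- scale(x, center = mu, scale = sdv)
    model$fit <- nn_train(model$net, xs, y, epochs = hp$epochs,
                          batch_size = hp$batch_size, lr = hp$lr,
                          seed = seed)
  } else if (fam == "cnn1d") {
    X <- vapply(x, function(s) {
      v <- if (inherits(s, "voice_signal")) s$samples else as.numeric(s)
      if (length(v) != hp$input_len) {
        stop("train_model: cnn1d inputs must have length ", hp$input_len)
      }
      v
    }, numeric(hp$input_len))
    orders <- vapply(seq_len(hp$epochs),
                     function(e) sample.int(ncol(X)), integer(ncol(X)))
    fit <- cpp_cnn1d_fit(X, y, r_net_to_cpp_weights(model$net), orders,
                         hp$batch_size, hp$lr)
    model$fit <- fit
    model$net <- cpp_weights_to_r_net(model$net, fit)
    model$net$history <- as.vector(fit$history)
  } else if (fam == "cnn2d") {
    xin <- lapply(x, function(p) {
      if (!is.matrix(p) || !all(dim(p) == c(40L, 40L))) {
        stop("train_model: cnn2d inputs must be 40x40 matrices")
      }
      matrix(as.vector(p), ncol = 1L)   # row-major 1600 x 1 channel map
    })
    model$fit <- nn_train(model$net, xin, y, epochs = hp$epochs,
                          batch_size = hp$batch_size, lr = hp$lr,
                          seed = seed)
  }
  model$hyper <- hp
  model$trained <- TRUE
  model
}

#' Predict class probabilities and labels
#'
#' Returns per-input probabilities for the two classes (summing to 1)
#' and the argmax label. For `cnn2d`, passing `groups` (one id per crop)
#' aggregates the crop probabilities of each recording by arithmetic
#' mean before the argmax; a tie at 0.5 is resolved to `"normal"`.
#'
#' @param model A trained `voxpath_model`.
#' @param x Inputs of the model's input kind.
#' @param groups Optional crop-to-recording ids (`cnn2d` only).
#' @return `data.frame` with columns `prob_normal`, `prob_pathological`,
#'   `label` (and `group` when aggregating).
#' @export
predict_model <- function(model, x, groups = NULL) {
  stopifnot(inherits(model, "voxpath_model"))
  if (!model$trained) stop("predict_model: model is not trained")
  fam <- model$config$family

  if (model$config$input_kind == "features") {
    x <- as.matrix(as.data.frame(x))
    storage.mode(x) <- "double"
    if (!is.null(model$feature_names)) {
      x <- x[, model$feature_names, drop = FALSE]
    }
  }

  p_path <- if (fam == "svm") {
    pr <- stats::predict(model$fit, x, probability = TRUE)
    attr(pr, "probabilities")[, "pathological"]
  } else if (fam %in% c("xgb", "lgbm")) {
    stats::predict(model$fit, xgboost::xgb.DMatrix(x))
  } else if (fam == "ann") {
    xs <- scale(x, center = model$scaling$mu, scale = model$scaling$sd)
    nn_predict_proba(model$fit, xs)[, 2L]
  } else if (fam == "cnn1d") {
    X <- vapply(x, function(s) {
      v <- if (inherits(s, "voice_signal")) s$samples else as.numeric(s)
      v
    }, numeric(model$hyper$input_len))
    cpp_cnn1d_predict(X, model$fit)[, 2L]
  } else if (fam == "cnn2d") {
    xin <- lapply(x, function(p) matrix(as.vector(p), ncol = 1L))
    nn_predict_proba(model$fit, xin)[, 2L]
  }

  out <- data.frame(prob_normal = 1 - p_path, prob_pathological = p_path)
  if (fam == "cnn2d" && !is.null(groups)) {
    agg <- model$hyper$aggregation
    sp <- split(out$prob_pathological, factor(groups, levels = unique(groups)))
    p_rec <- if (identical(agg, "vote")) {
      vapply(sp, function(p) mean(p > 0.5), numeric(1L))
    } else {
      vapply(sp, mean, numeric(1L))
    }
    out <- data.frame(group = names(sp), prob_normal = 1 - p_rec,
                      prob_pathological = p_rec)
  }
  out$label <- ifelse(out$prob_pathological > 0.5, "pathological", "normal")
  out
}

#' Information-gain feature importance
#'
#' Gain-based importance of a trained gradient-boosted model,
#' non-negative and normalized to sum to 1 over the 14 feature names
#' (features a tree never split on report 0).
#'
#' @param model A trained `voxpath_model` of family `xgb` or `lgbm`.
#' @return Named numeric vector over the training feature names, in
#'   decreasing order of importance.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "voxpath_model"))
  if (!model$config$family %in% c("xgb", "lgbm")) {
    stop("feature_importance: only tree-boosted families carry information gain")
  }
  if (!model$trained) stop("feature_importance: model is not trained")
  imp <- xgboost::xgb.importance(model = model$fit)
  out <- stats::setNames(numeric(length(model$feature_names)),
                         model$feature_names)
  out[imp$Feature] <- imp$Gain
  if (sum(out) > 0) out <- out / sum(out)
  sort(out, decreasing = TRUE)
}
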