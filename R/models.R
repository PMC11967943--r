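#' Classifier hyperparameter configuration
#'
#' One configuration object serves all six families; only the
#' family-appropriate fields are consulted. Neural defaults follow the
#' baseline `{batch 256, learning rate 1e-4, kernel 9, 100 epochs}`;
#' gradient-boosted trees default to `{100 trees, eta 0.3, depth 6}`;
#' random forests use 100 trees with unlimited depth.
#'
#' @param batch_size minibatch size for neural training.
#' @param learning_rate Adam learning rate (neural) .
#' @param kernel_size convolution kernel size (1-D families).
#' @param epochs number of training epochs.
#' @param n_estimators number of trees (gbt / rf).
#' @param eta boosting learning rate (gbt).
#' @param max_depth maximum tree depth (gbt; `NULL` = unlimited for rf).
#' @param dropout dropout probability for neural heads.
#' @param seed integer seed controlling initialisation and training order.
#' @return object of class `epg_model_config`.
#' @export
epg_model_config <- function(batch_size = 256, learning_rate = 1e-4,
                             kernel_size = 9, epochs = 100,
                             n_estimators = 100, eta = 0.3, max_depth = 6,
                             dropout = 0.5, seed = 1) {
  stopifnot(batch_size >= 1, learning_rate > 0, kernel_size >= 1,
            epochs >= 1, n_estimators >= 1, eta > 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 kernel_size = as.integer(kernel_size),
                 epochs = as.integer(epochs),
                 n_estimators = as.integer(n_estimators),
                 eta = eta, max_depth = max_depth, dropout = dropout,
                 seed = as.integer(seed)),
            class = "epg_model_config")
}

EPG_FAMILIES <- c("cnn1d", "resnet1d", "cnn2d", "gbt", "rf", "logreg")

#' Build the 1-D convolutional network
#'
#' Three convolutional layers with 64, 128 and 64 output channels, each
#' using dilation 3 and stride 2 followed by ReLU and batch normalisation,
#' then max pooling of size 3, flatten, dropout 0.5 and a fully connected
#' layer to the 7 classes. The flatten width is derived from shape
#' arithmetic, so segment lengths other than 1024 also build.
#'
#' @param d input segment length (default 1024).
#' @param config an [epg_model_config()]; `kernel_size` applies to all
#'   three convolutions.
#' @return internal network specification.
#' @export
build_cnn1d <- function(d = 1024, config = epg_model_config()) {
  k <- config$kernel_size
  with_seed(mix_seed(config$seed, 21L), {
    layers <- list()
    Cin <- 1L; L <- as.integer(d)
    for (Cout in c(64L, 128L, 64L)) {
      cv <- layer_conv1d(Cin, Cout, k, L, stride = 2L, dilation = 3L)
      layers <- c(layers, list(cv, layer_relu(), layer_bn(Cout)))
      Cin <- Cout; L <- cv$Lout
    }
    pool <- layer_pool1d(Cin, L, size = 3L)
    L <- pool$Lout
    layers <- c(layers, list(pool, layer_flatten(),
                             layer_dropout(config$dropout),
                             layer_dense(Cin * L, 7L)))
    list(layers = layers, input = "1d", d = as.integer(d), config = config,
         family = "cnn1d")
  })
}

#' Build the 1-D residual network
#'
#' Three skip-connection blocks with 64, 128 and 128 output channels. Each
#' block applies three same-padded convolutions (ReLU between them), adds
#' the block input through an identity or 1x1 projection shortcut, and
#' normalises the sum; each block is followed by max pooling with kernel 3
#' and stride 3. The head is flatten, dropout 0.5 and a fully connected
#' layer to 7 classes.
#'
#' @inheritParams build_cnn1d
#' @return internal network specification.
#' @export
build_resnet1d <- function(d = 1024, config = epg_model_config()) {
  k <- config$kernel_size
  with_seed(mix_seed(config$seed, 22L), {
    layers <- list()
    Cin <- 1L; L <- as.integer(d)
    for (Cout in c(64L, 128L, 128L)) {
      pad <- as.integer((k - 1L) %/% 2L)
      blk <- new_layer("resblock",
                       conv1 = layer_conv1d(Cin, Cout, k, L, pad = pad),
                       relu1 = layer_relu(),
                       conv2 = layer_conv1d(Cout, Cout, k, if (k %% 2L == 1L) L else L - 1L, pad = pad),
                       relu2 = layer_relu(),
                       conv3 = layer_conv1d(Cout, Cout, k, if (k %% 2L == 1L) L else L - 2L, pad = pad),
                       proj = if (Cin != Cout) layer_conv1d(Cin, Cout, 1L, L) else NULL,
                       bn = layer_bn(Cout))
      Lb <- blk$conv3$Lout
      pool <- layer_pool1d(Cout, Lb, size = 3L, stride = 3L)
      layers <- c(layers, list(blk, pool))
      Cin <- Cout; L <- pool$Lout
    }
    layers <- c(layers, list(layer_flatten(), layer_dropout(config$dropout),
                             layer_dense(Cin * L, 7L)))
    list(layers = layers, input = "1d", d = as.integer(d), config = config,
         family = "resnet1d")
  })
}

#' Build the 2-D convolutional network
#'
#' Two convolutional stages (16 channels, 3x3 kernel, stride 1, ReLU,
#' 2x2 max pooling with stride 2), then flatten and two fully connected
#' layers each preceded by dropout 0.5. Accepts 64x64 (GASF, scalogram)
#' or 65x65 (spectrogram) single-channel images.
#'
#' @param image_size side length of the square input image (64 or 65).
#' @param config an [epg_model_config()].
#' @return internal network specification.
#' @export
build_cnn2d <- function(image_size = 64, config = epg_model_config()) {
  if (!image_size %in% c(64L, 65L)) {
    stopf("cnn2d expects 64x64 or 65x65 images, got %dx%d",
          image_size, image_size)
  }
  with_seed(mix_seed(config$seed, 23L), {
    H <- as.integer(image_size)
    c1 <- layer_conv2d(1L, 16L, 3L, H, H)
    p1 <- layer_pool2d(16L, c1$Hout, c1$Wout)
    c2 <- layer_conv2d(16L, 16L, 3L, p1$Hout, p1$Wout)
    p2 <- layer_pool2d(16L, c2$Hout, c2$Wout)
    flat <- 16L * p2$Hout * p2$Wout
    layers <- list(c1, layer_relu(), p1, c2, layer_relu(), p2,
                   layer_flatten(),
                   layer_dropout(config$dropout), layer_dense(flat, 128L),
                   layer_relu(),
                   layer_dropout(config$dropout), layer_dense(128L, 7L))
    list(layers = layers, input = "2d", d = H, config = config,
         family = "cnn2d")
  })
}

#' Train a waveform classifier
#'
#' The single fitting entry point for all six families. Classical families
#' (`gbt`, `rf`, `logreg`) take a handcrafted feature matrix; neural
#' families take raw segments (`cnn1d`, `resnet1d`: segments x d matrix) or
#' image stacks (`cnn2d`: segments x rows x cols array). Neural families
#' minimise the cross-entropy loss with Adam at the configured batch size
#' and learning rate, recording per-epoch training/validation curves.
#' Training is reproducible under a fixed `config$seed`.
#'
#' @param x features: numeric matrix or 3-D image array, one row/slice per
#'   segment.
#' @param y segment labels (coercible via [as_epg_label()]).
#' @param family one of `"gbt"`, `"rf"`, `"logreg"`, `"cnn1d"`,
#'   `"resnet1d"`, `"cnn2d"`.
#' @param config an [epg_model_config()].
#' @param feature_kind the representation `x` was extracted with (see
#'   [segment_features()]); stored as the model's feature contract and
#'   applied automatically by [annotate_recording()].
#' @param val optional `list(x =, y =)` validation set (neural curves).
#' @return an object of class `epg_model`.
#' @export
epg_train <- function(x, y, family = c("gbt", "rf", "logreg", "cnn1d",
                                       "resnet1d", "cnn2d"),
                      config = epg_model_config(),
                      feature_kind = NULL, val = NULL) {
  family <- match.arg(family)
  y <- as_epg_label(y)
  n <- if (length(dim(x)) == 3) dim(x)[1] else nrow(x)
  if (n != length(y)) stopf("x has %d rows but y has %d labels", n, length(y))
  if (length(unique(y)) < 2) stopf("training labels contain a single class")
  if (is.null(feature_kind)) {
    feature_kind <- switch(family, gbt = , rf = , logreg = "stat_wt",
                           cnn2d = "gasf", "raw")
  }
  if (family %in% c("gbt", "rf", "logreg")) {
    fit <- fit_classical(family, x, y, config)
    model <- list(family = family, config = config, classes = EPG_LABELS,
                  feature_kind = feature_kind, n_features = ncol(x),
                  feature_names = colnames(x), fit = fit, curves = NULL)
  } else {
    spec <- switch(family,
      cnn1d = build_cnn1d(ncol(x), config),
      resnet1d = build_resnet1d(ncol(x), config),
      cnn2d = {
        if (length(dim(x)) != 3 || dim(x)[2] != dim(x)[3]) {
          stopf("cnn2d expects a (segments x size x size) image array")
        }
        build_cnn2d(dim(x)[2], config)
      })
    trained <- fit_neural(spec, x, y, config, val = val)
    model <- list(family = family, config = config, classes = EPG_LABELS,
                  feature_kind = feature_kind,
                  n_features = if (length(dim(x)) == 3) dim(x)[2] else ncol(x),
                  feature_names = NULL, fit = trained$net,
                  curves = trained$curves)
  }
  class(model) <- "epg_model"
  model
}

fit_classical <- function(family, x, y, config) {
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  switch(family,
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      booster <- xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = 7L,
                      eta = config$eta, max_depth = config$max_depth,
                      seed = config$seed, nthread = 1L),
        data = dtrain, nrounds = config$n_estimators, verbose = 0)
      list(kind = "gbt", booster = booster)
    },
    rf = {
      fit <- with_seed(mix_seed(config$seed, 31L),
        randomForest::randomForest(x = x, y = droplevels(y),
                                   ntree = config$n_estimators))
      list(kind = "rf", fit = fit, levels = levels(droplevels(y)))
    },
    logreg = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- droplevels(y)
      fit <- with_seed(mix_seed(config$seed, 32L),
        nnet::multinom(.y ~ ., data = df, trace = FALSE, decay = 1e-4,
                       MaxNWts = 100000, maxit = 200))
      list(kind = "logreg", fit = fit, levels = levels(droplevels(y)),
           feature_names = colnames(x))
    })
}

fit_neural <- function(spec, x, y, config, val = NULL) {
  yi <- as.integer(y)
  n <- if (length(dim(x)) == 3) dim(x)[1] else nrow(x)
  xin <- to_internal(x, spec$input)
  vin <- if (!is.null(val)) to_internal(val$x, spec$input)
  vyi <- if (!is.null(val)) as.integer(as_epg_label(val$y))
  curves <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                       train_acc = NA_real_, val_loss = NA_real_,
                       val_acc = NA_real_)
  with_seed(mix_seed(config$seed, 33L), {
    t_step <- 0L
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      losses <- c(); hits <- 0L
      for (b0 in seq(1, n, by = config$batch_size)) {
        ids <- perm[b0:min(n, b0 + config$batch_size - 1L)]
        xb <- xin[, , ids, drop = FALSE]
        logits <- nn_forward_list(spec, xb, training = TRUE)
        ls <- xent_loss(logits, yi[ids])
        if (!is.finite(ls$loss)) {
          stopf("training diverged (non-finite loss) at epoch %d", ep)
        }
        losses <- c(losses, ls$loss)
        hits <- hits + sum(apply(logits, 2, which.max) == yi[ids])
        dy <- ls$grad
        for (l in rev(spec$layers)) dy <- layer_backward(l, dy)
        t_step <- t_step + 1L
        adam_step(spec, config$learning_rate, t_step)
      }
      curves$train_loss[ep] <- mean(losses)
      curves$train_acc[ep] <- hits / n
      if (!is.null(val)) {
        vlog <- nn_forward_list(spec, vin, training = FALSE)
        vls <- xent_loss(vlog, vyi)
        curves$val_loss[ep] <- vls$loss
        curves$val_acc[ep] <- mean(apply(vlog, 2, which.max) == vyi)
      }
    }
  })
  list(net = spec, curves = curves)
}

nn_forward_list <- function(spec, x, training = FALSE) {
  for (l in spec$layers) x <- layer_forward(l, x, training)
  x
}

#' Class-probability predictions
#'
#' Returns one row per segment with the 7 class probabilities in canonical
#' order `NP, C, pd, E1, E2, F, G`; rows sum to 1. [predict.epg_model()] is
#' the method interface to the same computation.
#'
#' @param model an `epg_model`.
#' @param x feature batch matching the model's feature contract.
#' @return numeric matrix (segments x 7) with class-named columns.
#' @export
predict_proba <- function(model, x) {
  out <- switch(model$fit$kind %||% model$family,
    gbt = {
      p <- predict(model$fit$booster, xgboost::xgb.DMatrix(x))
      matrix(p, ncol = 7, dimnames = list(NULL, EPG_LABELS))
    },
    rf = {
      p <- predict(model$fit$fit, x, type = "prob")
      expand_class_columns(p, colnames(p))
    },
    logreg = {
      df <- data.frame(x, check.names = FALSE)
      p <- predict(model$fit$fit, df, type = "probs")
      if (is.null(dim(p))) p <- matrix(p, ncol = length(model$fit$levels),
                                       dimnames = list(NULL, model$fit$levels))
      expand_class_columns(p, colnames(p))
    },
    {
      # neural families: model$fit is the network spec
      xin <- to_internal(x, model$fit$input)
      logits <- nn_forward_list(model$fit, xin, training = FALSE)
      t(softmax_cols(logits))
    })
  colnames(out) <- EPG_LABELS
  rownames(out) <- NULL
  out
}

expand_class_columns <- function(p, have) {
  out <- matrix(0, nrow(p), 7, dimnames = list(NULL, EPG_LABELS))
  out[, have] <- as.matrix(p)
  out
}

#' Predicted labels or probabilities
#'
#' @param object an `epg_model`.
#' @param newdata feature batch matching the model's feature contract.
#' @param type `"class"` (default) for hard labels with ties broken by
#'   canonical class order, or `"prob"` for the probability matrix.
#' @param ... unused.
#' @export
predict.epg_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") return(p)
  # max.col with ties.method = "first" = canonical-order tie-break
  factor(EPG_LABELS[max.col(p, ties.method = "first")], levels = EPG_LABELS)
}

#' @export
print.epg_model <- function(x, ...) {
  cat(sprintf("<epg_model: family=%s, features=%s (%s), 7 classes>\n",
              x$family, x$feature_kind,
              paste(x$n_features, collapse = "x")))
  invisible(x)
}

#' @export
summary.epg_model <- function(object, ...) {
  print(object)
  cat("class order:", paste(object$classes, collapse = " < "), "\n")
  if (!is.null(object$curves)) {
    cat(sprintf("trained %d epochs; final train loss %.4f, train acc %.3f\n",
                nrow(object$curves),
                utils::tail(object$curves$train_loss, 1),
                utils::tail(object$curves$train_acc, 1)))
  }
  if (object$family %in% c("cnn1d", "resnet1d", "cnn2d")) {
    cat(sprintf("parameters: %d\n", nn_count_params(object$fit)))
  }
  invisible(object)
}

#' Save a trained model archive
#'
#' Writes a directory containing `meta.json` (family, configuration, class
#' order, feature contract, format version) and the fitted parameters.
#'
#' @param model an `epg_model`.
#' @param path directory to create.
#' @export
save_epg_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(version = 1L, family = model$family,
               config = unclass(model$config), classes = model$classes,
               feature_kind = model$feature_kind,
               n_features = model$n_features,
               feature_names = model$feature_names)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       null = "null")
  if (model$family == "gbt") {
    saveRDS(xgboost::xgb.save.raw(model$fit$booster),
            file.path(path, "payload.rds"))
  } else if (model$family %in% c("rf", "logreg")) {
    saveRDS(model$fit, file.path(path, "payload.rds"))
  } else if (model$family == "oracle") {
    saveRDS(model$track, file.path(path, "payload.rds"))
  } else {
    saveRDS(list(state = nn_get_state(model$fit), d = model$fit$d),
            file.path(path, "payload.rds"))
  }
  invisible(path)
}

#' Load a model archive written by [save_epg_model()]
#'
#' @param path archive directory.
#' @return an `epg_model`.
#' @export
load_epg_model <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stopf("not a model archive (missing meta.json): %s", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  config <- do.call(epg_model_config, meta$config[names(meta$config) %in%
    names(formals(epg_model_config))])
  payload <- readRDS(file.path(path, "payload.rds"))
  fit <- switch(meta$family,
    gbt = list(kind = "gbt", booster = xgboost::xgb.load.raw(payload)),
    rf = payload,
    logreg = payload,
    oracle = NULL,
    {
      spec <- switch(meta$family,
        cnn1d = build_cnn1d(payload$d, config),
        resnet1d = build_resnet1d(payload$d, config),
        cnn2d = build_cnn2d(payload$d, config))
      nn_set_state(spec, payload$state)
      spec
    })
  model <- list(family = meta$family, config = config, classes = meta$classes,
                feature_kind = meta$feature_kind,
                n_features = meta$n_features,
                feature_names = meta$feature_names, fit = fit, curves = NULL)
  if (meta$family == "oracle") model$track <- payload
  class(model) <- "epg_model"
  model
}

nn_get_state <- function(net) {
  lapply(collect_layers(net$layers), function(l) {
    s <- list()
    for (p in c(layer_params(l), if (l$type == "bn") c("run_mean", "run_var"))) {
      s[[p]] <- get(p, envir = l)
    }
    s
  })
}

nn_set_state <- function(net, state) {
  ls <- collect_layers(net$layers)
  stopifnot(length(ls) == length(state))
  for (i in seq_along(ls)) {
    for (p in names(state[[i]])) {
      cur <- get(p, envir = ls[[i]])
      val <- state[[i]][[p]]
      if (is.matrix(cur)) val <- matrix(val, nrow(cur), ncol(cur))
      assign(p, val, envir = ls[[i]])
    }
  }
  invisible(net)
}

#' Oracle classifier that reproduces the ground truth
#'
#' A diagnostic model carrying the true annotation track: when pushed
#' through [annotate_recording()] it labels each segment with the majority
#' ground-truth label, so on tracks aligned to segment boundaries it
#' recovers an overlap rate of exactly 1.
#'
#' @param track the ground-truth [epg_track()].
#' @return an `epg_model` of family `"oracle"`.
#' @export
epg_oracle_model <- function(track) {
  structure(list(family = "oracle", config = NULL, classes = EPG_LABELS,
                 feature_kind = "raw", n_features = NA_integer_,
                 feature_names = NULL, fit = NULL, curves = NULL,
                 track = track),
            class = "epg_model")
}

#' Hyperparameter search
#'
#' Two strategies mirror how the two representative families are tuned:
#' `gbt` uses an exhaustive grid over `n_estimators` x `eta` x `max_depth`
#' (the default grids give 4 x 4 x 4 = 64 runs); `cnn1d` uses a sequential
#' one-factor sweep in the fixed order batch size, learning rate, kernel
#' size, epochs (default grids: 6 + 4 + 3 + 3 = 16 scheduled runs, repeated
#' configurations evaluated once via a cache). The selection criterion is
#' validation accuracy; ties go to the earlier (smaller) configuration.
#'
#' @param family `"gbt"` or `"cnn1d"`.
#' @param data list with `train_x`, `train_y`, `val_x`, `val_y`.
#' @param grid named list of parameter vectors; defaults are the standard
#'   tuning ranges for each family.
#' @param config base [epg_model_config()] supplying untuned fields.
#' @param eval_fn optional `function(config, data) -> validation accuracy`;
#'   defaults to training the family and scoring on the validation set.
#'   Injectable for cheap schedule tests and custom metrics.
#' @return list with `best_config`, `best_score`, and `results` (one row
#'   per scheduled run).
#' @export
grid_search <- function(family = c("gbt", "cnn1d"), data, grid = NULL,
                        config = epg_model_config(), eval_fn = NULL) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- if (family == "gbt") {
      list(n_estimators = c(50, 100, 200, 300), eta = c(0.01, 0.1, 0.2, 0.3),
           max_depth = c(3, 4, 5, 6))
    } else {
      list(batch_size = c(128, 256, 512, 1024, 2048, 4096),
           learning_rate = c(1e-2, 1e-3, 1e-4, 1e-5),
           kernel_size = c(5, 9, 15), epochs = c(20, 50, 100))
    }
  }
  if (any(vapply(grid, length, integer(1)) == 0)) stopf("empty grid")
  if (is.null(eval_fn)) {
    eval_fn <- function(cfg, data) {
      m <- epg_train(data$train_x, data$train_y, family = family, config = cfg)
      mean(predict(m, data$val_x) == as_epg_label(data$val_y))
    }
  }
  cache <- new.env(parent = emptyenv())
  evaluate <- function(cfg) {
    key <- paste(cfg$batch_size, cfg$learning_rate, cfg$kernel_size,
                 cfg$epochs, cfg$n_estimators, cfg$eta, cfg$max_depth,
                 sep = "|")
    if (!exists(key, envir = cache)) {
      assign(key, eval_fn(cfg, data), envir = cache)
    }
    get(key, envir = cache)
  }
  results <- list()
  push <- function(cfg, score) {
    results[[length(results) + 1L]] <<- data.frame(
      batch_size = cfg$batch_size, learning_rate = cfg$learning_rate,
      kernel_size = cfg$kernel_size, epochs = cfg$epochs,
      n_estimators = cfg$n_estimators, eta = cfg$eta,
      max_depth = if (is.null(cfg$max_depth)) NA else cfg$max_depth,
      val_accuracy = score)
  }
  best <- config; best_score <- -Inf
  if (family == "gbt") {
    for (ne in grid$n_estimators) for (et in grid$eta) for (md in grid$max_depth) {
      cfg <- best_with(config, n_estimators = ne, eta = et, max_depth = md)
      sc <- evaluate(cfg)
      push(cfg, sc)
      if (sc > best_score) { best <- cfg; best_score <- sc }
    }
  } else {
    cur <- config
    for (param in c("batch_size", "learning_rate", "kernel_size", "epochs")) {
      sweep_best <- NULL; sweep_score <- -Inf
      for (v in grid[[param]]) {
        cfg <- do.call(best_with, c(list(cur), stats::setNames(list(v), param)))
        sc <- evaluate(cfg)
        push(cfg, sc)
        if (sc > sweep_score) { sweep_best <- cfg; sweep_score <- sc }
      }
      cur <- sweep_best
    }
    best <- cur
    best_score <- evaluate(cur)
  }
  list(best_config = best, best_score = best_score,
       results = do.call(rbind, results))
}

best_with <- function(config, ...) {
  mods <- list(...)
  for (nm in names(mods)) config[[nm]] <- mods[[nm]]
  config
}
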