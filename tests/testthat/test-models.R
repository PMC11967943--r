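test_that("classical families behave as null models on pure noise", {
  with_test_seed(51, {
    n <- 2000
    x <- matrix(stats::rnorm(n * 10), n,
                dimnames = list(NULL, paste0("f", 1:10)))
    y <- factor(sample(c("NP", "C", "E2"), n, TRUE,
                       prob = c(0.6, 0.25, 0.15)), levels = EPG_LABELS)
    xtest <- matrix(stats::rnorm(n * 10), n,
                    dimnames = list(NULL, paste0("f", 1:10)))
    ytest <- factor(sample(c("NP", "C", "E2"), n, TRUE,
                           prob = c(0.6, 0.25, 0.15)), levels = EPG_LABELS)
    majority <- mean(ytest == "NP")
    for (fam in c("gbt", "rf", "logreg")) {
      m <- epg_train(x, y, family = fam, config = epg_model_config(seed = 1))
      acc <- mean(predict(m, xtest) == ytest)
      expect_lt(abs(acc - majority), 0.05)
    }
  })
})

test_that("classical families separate well-separated clusters", {
  with_test_seed(52, {
    n <- 200
    centers <- matrix(stats::rnorm(3 * 8, sd = 6), 3)
    x <- do.call(rbind, lapply(1:3, function(k) {
      sweep(matrix(stats::rnorm(n * 8, sd = 0.5), n), 2, centers[k, ], `+`)
    }))
    colnames(x) <- paste0("f", 1:8)
    y <- factor(rep(c("C", "E2", "G"), each = n), levels = EPG_LABELS)
    test_idx <- sample(3 * n, 150)
    for (fam in c("gbt", "rf", "logreg")) {
      m <- epg_train(x[-test_idx, ], y[-test_idx], family = fam,
                     config = epg_model_config(seed = 2))
      expect_gt(mean(predict(m, x[test_idx, ]) == y[test_idx]), 0.95)
    }
  })
})

test_that("probability predictions are normalised with canonical argmax", {
  with_test_seed(53, {
    x <- matrix(stats::rnorm(100 * 5), 100,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- factor(sample(c("NP", "pd", "F"), 100, TRUE), levels = EPG_LABELS)
    m <- epg_train(x, y, family = "gbt", config = epg_model_config(seed = 3))
    p <- predict_proba(m, x)
    expect_equal(dim(p), c(100, 7))
    expect_equal(colnames(p), EPG_LABELS)
    expect_equal(rowSums(p), rep(1, 100), tolerance = 1e-6)
    expect_true(all(p >= 0))
    # argmax agrees with a brute-force max scan
    hard <- predict(m, x)
    for (i in sample(100, 20)) {
      expect_equal(as.character(hard[i]),
                   EPG_LABELS[which(p[i, ] == max(p[i, ]))[1]])
    }
    # rf/logreg trained on a class subset still emit all 7 columns
    m2 <- epg_train(x, y, family = "rf", config = epg_model_config(seed = 3))
    p2 <- predict_proba(m2, x)
    expect_equal(dim(p2), c(100, 7))
    expect_true(all(p2[, c("C", "E1", "E2", "G")] == 0))
  })
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(stats::rnorm(40), 10)
  y <- factor(rep("C", 10), levels = EPG_LABELS)
  expect_error(epg_train(x, y, family = "gbt"), "single class")
  expect_error(epg_train(x, factor(c("C"), levels = EPG_LABELS),
                         family = "gbt"), "rows")
})

test_that("fixed seeds reproduce identical predictions", {
  with_test_seed(54, {
    x <- matrix(stats::rnorm(300 * 6), 300,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- factor(sample(c("NP", "C", "E2"), 300, TRUE), levels = EPG_LABELS)
    for (fam in c("gbt", "rf")) {
      m1 <- epg_train(x, y, family = fam, config = epg_model_config(seed = 11))
      m2 <- epg_train(x, y, family = fam, config = epg_model_config(seed = 11))
      expect_identical(predict_proba(m1, x), predict_proba(m2, x))
    }
  })
})

test_that("grid search enumerates the documented schedules", {
  fake_eval <- function(cfg, data) {
    # deterministic surrogate score, maximised at a known config
    -abs(log10(cfg$learning_rate) + 3) - abs(cfg$batch_size - 512) / 1024 -
      abs(cfg$kernel_size - 9) / 10 - abs(cfg$epochs - 50) / 100 -
      abs(cfg$n_estimators - 200) / 100 - abs(cfg$eta - 0.2) -
      abs((cfg$max_depth %||% 6) - 5)
  }
  gs <- grid_search("gbt", data = NULL, eval_fn = fake_eval)
  expect_equal(nrow(gs$results), 64)           # 4 x 4 x 4 exhaustive
  expect_equal(gs$best_config$n_estimators, 200)
  expect_equal(gs$best_config$eta, 0.2)
  expect_equal(gs$best_config$max_depth, 5)

  calls <- new.env(); calls$n <- 0
  counting_eval <- function(cfg, data) { calls$n <- calls$n + 1; fake_eval(cfg, data) }
  gc1 <- grid_search("cnn1d", data = NULL, eval_fn = counting_eval)
  expect_equal(nrow(gc1$results), 16)          # 6 + 4 + 3 + 3 scheduled runs
  expect_lt(calls$n, 16)                       # overlaps deduplicated
  expect_equal(gc1$best_config$batch_size, 512)
  expect_equal(gc1$best_config$learning_rate, 1e-3)
  expect_equal(gc1$best_config$kernel_size, 9)
  expect_equal(gc1$best_config$epochs, 50)

  g1 <- grid_search("gbt", data = NULL, eval_fn = fake_eval,
                    grid = list(n_estimators = 100, eta = 0.3, max_depth = 6))
  expect_equal(nrow(g1$results), 1)
  expect_error(grid_search("gbt", data = NULL, eval_fn = fake_eval,
                           grid = list(n_estimators = numeric(0),
                                       eta = 0.3, max_depth = 6)), "empty")
})

test_that("model archives round-trip predictions for all family kinds", {
  with_test_seed(55, {
    x <- matrix(stats::rnorm(200 * 6), 200,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- factor(sample(c("NP", "C", "G"), 200, TRUE), levels = EPG_LABELS)
    for (fam in c("gbt", "rf", "logreg")) {
      m <- epg_train(x, y, family = fam, config = epg_model_config(seed = 7),
                     feature_kind = "stat_raw")
      dir <- withr::local_tempdir()
      save_epg_model(m, dir)
      back <- load_epg_model(dir)
      expect_equal(back$feature_kind, "stat_raw")
      expect_equal(predict_proba(back, x), predict_proba(m, x),
                   tolerance = 1e-12)
    }
    toy <- toy_separable(n_per_class = 16, d = 256)
    cfg <- epg_model_config(epochs = 3, batch_size = 16, learning_rate = 1e-3,
                            seed = 8)
    mn <- epg_train(toy$x, toy$y, family = "cnn1d", config = cfg)
    dir <- withr::local_tempdir()
    save_epg_model(mn, dir)
    backn <- load_epg_model(dir)
    expect_equal(predict_proba(backn, toy$x), predict_proba(mn, toy$x),
                 tolerance = 1e-10)
    expect_error(load_epg_model(withr::local_tempdir()), "meta.json")
  })
})
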