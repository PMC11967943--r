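test_that("confusion matrices tally truth against prediction", {
  y <- factor(sample(EPG_LABELS, 500, TRUE), levels = EPG_LABELS)
  cm <- confusion_matrix(y, y)
  expect_equal(diag(unclass(cm)), as.vector(table(y)), ignore_attr = TRUE)
  expect_equal(sum(cm) - sum(diag(unclass(cm))), 0)

  pred_all_c <- factor(rep("C", 500), levels = EPG_LABELS)
  cm2 <- confusion_matrix(y, pred_all_c)
  expect_true(all(cm2[, setdiff(EPG_LABELS, "C")] == 0))
  expect_equal(rowSums(cm2), as.vector(table(y)), ignore_attr = TRUE)
  expect_error(confusion_matrix(y, y[-1]), "length")
})

test_that("metrics match their definitional hand computation", {
  y <- factor(sample(EPG_LABELS, 300, TRUE), levels = EPG_LABELS)
  diagm <- confusion_matrix(y, y)
  md <- classification_metrics(diagm)
  expect_equal(md$overall_accuracy, 1)
  expect_equal(md$macro_f1, 1)

  # 2-class block [[40,10],[20,30]] embedded in the 7-class matrix
  truth <- c(rep("NP", 50), rep("C", 50))
  pred <- c(rep("NP", 40), rep("C", 10), rep("NP", 20), rep("C", 30))
  met <- suppressWarnings(classification_metrics(confusion_matrix(truth, pred)))
  expect_equal(met$overall_accuracy, 0.7)
  expect_equal(unname(met$per_class_f1["NP"]), 40 / (40 + 0.5 * (10 + 20)),
               tolerance = 1e-12)

  with_test_seed(61, {
    for (rep in 1:10) {
      t <- sample(EPG_LABELS[1:5], 200, TRUE)
      p <- sample(EPG_LABELS, 200, TRUE)
      m <- suppressWarnings(classification_metrics(confusion_matrix(t, p)))
      ref <- bf_metrics(factor(t, levels = EPG_LABELS),
                        factor(p, levels = EPG_LABELS))
      expect_equal(m$overall_accuracy, ref$oa, tolerance = 1e-12)
      expect_equal(unname(m$per_class_accuracy), unname(ref$recall),
                   tolerance = 1e-12)
      expect_equal(m$macro_f1, ref$macro_f1, tolerance = 1e-12)
    }
  })
  expect_warning(
    classification_metrics(confusion_matrix(rep("NP", 5), rep("NP", 5))),
    "absent")
})

test_that("overlap rate is per-timestep agreement", {
  a <- factor(rep(c("NP", "C"), each = 50), levels = EPG_LABELS)
  b <- factor(rep(c("C", "NP"), each = 50), levels = EPG_LABELS)
  expect_equal(overlap_rate(a, a), 1)
  expect_equal(overlap_rate(a, b), 0)
  expect_equal(overlap_rate(b, a), overlap_rate(a, b))  # symmetry
  expect_error(overlap_rate(a, a[-1]), "length")
  with_test_seed(62, {
    t <- factor(sample(EPG_LABELS, 400, TRUE), levels = EPG_LABELS)
    p <- factor(sample(EPG_LABELS, 400, TRUE), levels = EPG_LABELS)
    cm <- suppressWarnings(classification_metrics(confusion_matrix(t, p)))
    expect_equal(overlap_rate(t, p), cm$overall_accuracy)  # definitional tie
  })
})

test_that("annotation conserves labels and aligns to window boundaries", {
  cfg <- epg_sim_config(duration = 120, seed = 13)
  track <- sample_behavior_sequence(cfg)
  rec <- render_recording(track, cfg)
  oracle <- epg_oracle_model(track)
  ann <- annotate_recording(oracle, rec, d = 1024)
  expect_length(ann$labels, length(rec$samples))       # label conservation
  bounds <- ann$track$start_time[-1]
  expect_true(all(abs(bounds %% (1024 / 100)) < 1e-9))

  # single-class recording: the oracle recovers OR = 1 exactly
  flat <- epg_track("G", 0, end_time = 120)
  ann2 <- annotate_recording(epg_oracle_model(flat), rec, d = 1024)
  truth2 <- track_to_labels(flat, length(rec$samples), 100)
  expect_identical(overlap_rate(truth2, ann2$labels), 1)
})

test_that("a trained model annotates a separable recording accurately", {
  # alternating NP / G blocks aligned to the window grid
  d <- 512; rate <- 100
  blocks <- 24
  cfg <- epg_sim_config(duration = blocks * d / rate, rate = rate, seed = 14)
  labs <- rep(c("NP", "G"), length.out = blocks)
  track <- epg_track(labs, (seq_len(blocks) - 1) * d / rate,
                     end_time = blocks * d / rate)
  rec <- render_recording(track, cfg)
  segs <- segment_recording(normalize_recording(rec), d = d, s = d)
  truth <- track_to_labels(track, length(rec$samples), rate)
  y <- label_segments(segs, truth)
  fx <- segment_features(segs, "stat_wt")
  m <- epg_train(fx, y, family = "gbt", config = epg_model_config(seed = 1),
                 feature_kind = "stat_wt")
  ann <- annotate_recording(m, rec, d = d)
  expect_gt(overlap_rate(truth, ann$labels), 0.95)
})

test_that("k-fold evaluation partitions the data reproducibly", {
  with_test_seed(63, {
    n <- 240
    centers <- matrix(stats::rnorm(3 * 6, sd = 6), 3)
    x <- do.call(rbind, lapply(1:3, function(k) {
      sweep(matrix(stats::rnorm(n / 3 * 6, sd = 0.5), n / 3), 2,
            centers[k, ], `+`)
    }))
    colnames(x) <- paste0("f", 1:6)
    y <- factor(rep(c("C", "E2", "G"), each = n / 3), levels = EPG_LABELS)
    r <- kfold_evaluate(x, y, family = "gbt", k = 4,
                        config = epg_model_config(seed = 2), seed = 5)
    expect_equal(sort(unique(r$fold_assignment)), 1:4)
    expect_equal(length(r$fold_assignment), n)          # union = all
    expect_equal(sum(r$folds$n_test), n)                # disjoint partition
    expect_gt(r$summary$mean[r$summary$metric == "overall_accuracy"], 0.95)
    r2 <- kfold_evaluate(x, y, family = "gbt", k = 4,
                         config = epg_model_config(seed = 2), seed = 5)
    expect_identical(r$fold_assignment, r2$fold_assignment)
    expect_error(kfold_evaluate(x, y, k = 500), "exceeds")

    groups <- rep(1:12, each = 20)
    rg <- kfold_evaluate(x, y, family = "gbt", k = 3,
                         config = epg_model_config(seed = 2),
                         groups = groups, seed = 6)
    # group folding keeps each recording's segments in one fold
    for (g in unique(groups)) {
      expect_length(unique(rg$fold_assignment[groups == g]), 1)
    }
  })
})
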