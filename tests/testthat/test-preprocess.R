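test_that("min-max normalisation maps extremes to 0 and 1", {
  rec <- epg_recording(c(-1, 0, 1))
  expect_equal(normalize_recording(rec)$samples, c(0, 0.5, 1))
  expect_warning(z <- normalize_recording(epg_recording(c(5, 5, 5))), "constant")
  expect_equal(z$samples, c(0, 0, 0))
  with_test_seed(2, {
    for (rep in 1:20) {
      v <- stats::rnorm(sample(10:500, 1), sd = stats::runif(1, 0.1, 50))
      out <- normalize_recording(epg_recording(v))$samples
      expect_equal(range(out), c(0, 1))
    }
  })
})

test_that("segmentation tiles the recording and pads the trailing window", {
  rec <- epg_recording(stats::rnorm(2048))
  segs <- segment_recording(rec, d = 1024, s = 1024)
  expect_equal(nrow(segs$values), 2)
  expect_equal(segs$starts, c(0, 1024))
  expect_equal(as.vector(t(segs$values)), rec$samples)  # tiling, no overlap

  rec2 <- epg_recording(seq_len(2500))
  segs2 <- segment_recording(rec2, d = 1024, s = 1024)
  expect_equal(nrow(segs2$values), 3)                   # ceiling(2500/1024)
  expect_equal(segs2$values[3, 1:452], 2049:2500)
  expect_equal(segs2$values[3, 453:1024], rep(2500, 572))  # edge padding

  short <- segment_recording(epg_recording(1:10), d = 16, s = 16)
  expect_equal(nrow(short$values), 1)
  expect_equal(short$values[1, ], c(1:10, rep(10, 6)))

  # segment-count law at full scale: an 8 h 100 Hz recording gives 2813
  n8 <- 8 * 3600 * 100
  expect_equal(as.integer(ceiling((n8 - 1024) / 1024)) + 1L, 2813L)
})

test_that("segments are labelled by majority with canonical tie-break", {
  n <- 2048
  rec <- epg_recording(stats::rnorm(n))
  segs <- segment_recording(rec, d = 1024, s = 1024)

  truth <- factor(rep("C", n), levels = EPG_LABELS)
  expect_equal(as.character(label_segments(segs, truth)), c("C", "C"))

  truth2 <- factor(c(rep("C", 600), rep("pd", 424), rep("C", 1024)),
                   levels = EPG_LABELS)
  expect_equal(as.character(label_segments(segs, truth2))[1], "C")

  truth3 <- factor(c(rep("E1", 512), rep("C", 512), rep("C", 1024)),
                   levels = EPG_LABELS)
  # 512 C vs 512 E1: canonical order NP < C < pd < E1 < ... breaks the tie
  expect_equal(as.character(label_segments(segs, truth3))[1], "C")
})

test_that("midpoint padding follows the centred-window index arithmetic", {
  rec <- epg_recording(seq_len(4000))
  d <- 1024
  # occurrence [100, 300): centred window would start at -311, shifted to 0
  w <- pad_sample(rec, 100, 300, d)
  expect_equal(w$start, 0)
  expect_length(w$values, d)
  expect_equal(w$values, rec$samples[1:1024])
  # interior occurrence: window centred on m = floor((i+j)/2)
  w2 <- pad_sample(rec, 2000, 2200, d)
  m <- floor((2000 + 2200) / 2)
  expect_equal(w2$start, m - d / 2 + 1)
  # full-length occurrence is returned unchanged
  w3 <- pad_sample(rec, 1000, 1000 + d, d)
  expect_equal(w3$start, 1000)
  expect_equal(w3$values, rec$samples[1001:(1000 + d)])
  expect_error(pad_sample(epg_recording(1:100), 0, 50, 1024), "shorter")
  # contract: output length d for random valid occurrences
  with_test_seed(3, {
    for (rep in 1:20) {
      i <- sample(0:3000, 1); j <- i + sample(1:1000, 1)
      expect_length(pad_sample(rec, i, j, d)$values, d)
    }
  })
})

test_that("pd oversampling obeys the 2d/s + 1 count law", {
  rec <- epg_recording(seq_len(8000))
  ws <- oversample_pd(rec, 3000, 3500, d = 1024, s = 128)
  expect_length(ws, 2 * 1024 / 128 + 1)  # 17
  expect_length(oversample_pd(rec, 3000, 3500, d = 1024, s = 2048), 2)
  m <- floor((3000 + 3500) / 2)
  for (w in ws) {
    expect_length(w$values, 1024)
    # never fabricates values: windows are verbatim slices of the parent
    expect_equal(w$values, rec$samples[(w$start + 1):(w$start + 1024)])
    expect_gte(w$start, max(0, m - 1024 + 1))
    expect_lte(w$start + 1024, min(length(rec$samples), m + 2 * 1024) + 1024)
  }
  # property: randomised valid (d, s)
  with_test_seed(4, {
    for (rep in 1:25) {
      d <- sample(c(64, 128, 256, 512, 1024), 1)
      s <- sample(c(8, 16, 32, 64, 128, 2 * d), 1)
      i <- sample(2000:4000, 1); j <- i + sample(50:400, 1)
      out <- oversample_pd(rec, i, j, d = d, s = s)
      expect_length(out, (2 * d) %/% s + 1)
      expect_true(all(lengths(lapply(out, `[[`, "values")) == d))
    }
  })
})

test_that("the dataset split holds out recordings and conserves segments", {
  cfg <- epg_sim_config(duration = 120, seed = 6)
  pairs <- generate_dataset(10, cfg)
  sp <- split_dataset(pairs, split_spec(seed = 2), d = 1024,
                      oversample = FALSE)
  expect_length(sp$holdout, 1)          # round(0.1 * 10)
  n_each <- ceiling((120 * 100 - 1024) / 1024) + 1
  expect_equal(sp$n_segments, 9 * n_each)
  expect_equal(nrow(sp$train_x) + nrow(sp$val_x) + nrow(sp$test_x),
               sp$n_segments)           # conservation before augmentation
  sp2 <- split_dataset(pairs, split_spec(seed = 2), d = 1024,
                       oversample = FALSE)
  expect_identical(sp$holdout_idx, sp2$holdout_idx)
  expect_identical(sp$train_y, sp2$train_y)
  expect_error(split_dataset(pairs[1], split_spec()), "at least 2")

  # oversampling only ever grows the training portion
  spo <- split_dataset(pairs, split_spec(seed = 2), d = 1024,
                       oversample = TRUE, pd_stride = 512)
  expect_identical(spo$val_y, sp$val_y)
  expect_identical(spo$test_y, sp$test_y)
  expect_gte(nrow(spo$train_x), nrow(sp$train_x))
  extra <- seq(nrow(sp$train_x) + 1, nrow(spo$train_x))
  expect_true(all(spo$train_y[extra] == "pd"))
})
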