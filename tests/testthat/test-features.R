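test_that("the 13 handcrafted statistics match a brute-force reference", {
  with_test_seed(21, {
    for (rep in 1:25) {
      v <- stats::rnorm(sample(50:500, 1), mean = stats::runif(1, -2, 2),
                        sd = stats::runif(1, 0.1, 5))
      expect_equal(stat_features(v), bf_stat_features(v), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  })
})

test_that("degenerate and sign-structured inputs give the stated statistics", {
  expect_warning(f <- stat_features(rep(3, 100)), "constant")
  expect_equal(unname(f[c("mean", "sd", "zcr", "skew",
                          "shannon_entropy", "perm_entropy")]),
               c(3, 0, 0, 0, 0, 0))
  alt <- rep(c(-1, 1), 512)
  expect_equal(unname(stat_features(alt)["zcr"]), 1)
  expect_error(stat_features(c(1, 2)), "at least 4")
})

test_that("Shannon entropy of the energy distribution is exact", {
  onehot <- c(0, 0, 5, 0)
  expect_equal(shannon_entropy(onehot), 0)
  expect_equal(shannon_entropy(rep(2, 16)), log(16))
  expect_warning(z <- shannon_entropy(rep(0, 8)), "all-zero")
  expect_equal(z, 0)
  with_test_seed(22, {
    for (rep in 1:25) {
      v <- stats::rnorm(sample(20:200, 1))
      expect_equal(shannon_entropy(v), bf_shannon(v), tolerance = 1e-12)
    }
  })
})

test_that("permutation entropy counts ordinal patterns correctly", {
  expect_equal(permutation_entropy(1:100), 0)
  expect_error(permutation_entropy(c(1, 2, 3)), "too short")
  with_test_seed(23, {
    for (rep in 1:25) {
      v <- stats::rnorm(50)
      expect_equal(permutation_entropy(v), bf_perm_entropy(v),
                   tolerance = 1e-12)
    }
    noise <- stats::runif(1e4)
    expect_gt(permutation_entropy(noise), 0.98)
  })
})

test_that("Fourier magnitudes locate tones and satisfy Parseval", {
  d <- 1024
  t <- seq_len(d) - 1
  tone <- sin(2 * pi * 37 * t / d)
  mag <- fourier_magnitude(tone)
  expect_length(mag, d / 2 + 1)
  expect_equal(which.max(mag) - 1, 37)
  flat <- fourier_magnitude(rep(2, d))
  expect_equal(which.max(flat), 1)
  expect_lt(max(flat[-1]), 1e-8)
  with_test_seed(24, {
    v <- stats::rnorm(d)
    m <- fourier_magnitude(v)
    energy_freq <- (m[1]^2 + 2 * sum(m[2:(d / 2)]^2) + m[d / 2 + 1]^2) / d
    expect_equal(energy_freq, sum(v^2), tolerance = 1e-6)
  })
})

test_that("the spectrogram has the stated 65 x 65 geometry", {
  expect_equal((1024 - 128) / 14 + 1, 65)  # frame arithmetic
  expect_equal(128 / 2 + 1, 65)            # rFFT bins
  v <- with_test_seed(25, stats::rnorm(1024))
  img <- spectrogram_image(v)
  expect_equal(dim(img), c(65, 65))
  # a chirp produces a monotone ridge across frames
  t <- (0:1023) / 100
  chirp <- sin(2 * pi * (2 * t + 1.5 * t^2))
  ridge <- apply(spectrogram_image(chirp), 2, which.max)
  expect_true(all(diff(ridge) >= 0))
  expect_gt(ridge[65], ridge[1])
  expect_warning(img2 <- spectrogram_image(stats::rnorm(512)), "resized")
  expect_equal(dim(img2), c(65, 65))
})

test_that("the symlet-4 decomposition is invertible with vanishing details", {
  v <- with_test_seed(26, stats::rnorm(1024))
  b <- dwt_multires(v)
  expect_named(b, c("A3", "D3", "D2", "D1"))
  expect_equal(dwt_reconstruct(b), v, tolerance = 1e-8)
  # coefficient counts halve per level, plus the filter overhang
  expect_equal(lengths(b)[c("D1", "D2", "D3")],
               c(D1 = 515, D2 = 261, D3 = 134))
  flat <- dwt_multires(rep(4, 256))
  expect_lt(max(abs(flat$D1)), 1e-10)
  expect_lt(max(abs(flat$D2)), 1e-10)
  expect_lt(max(abs(flat$D3)), 1e-10)
})

test_that("wavelet features are the concatenated per-band statistics", {
  v <- with_test_seed(27, stats::rnorm(1024))
  w <- wavelet_features(v)
  expect_length(w, 52)
  b <- dwt_multires(v)
  manual <- c(stat_features(b$A3, "A3"), stat_features(b$D3, "D3"),
              stat_features(b$D2, "D2"), stat_features(b$D1, "D1"))
  expect_identical(w, manual)
  expect_true(all(grepl("^(A3|D3|D2|D1)\\.", names(w))))
  suppressWarnings(wf <- wavelet_features(rep(2, 1024)))
  detail <- wf[grepl("^D[123]\\.(sd|zcr|shannon_entropy|perm_entropy)", names(wf))]
  expect_lt(max(abs(detail)), 1e-10)
})

test_that("the scalogram maps tones to their matching scale row", {
  z <- scalogram_image(rep(0, 1024))
  expect_equal(dim(z), c(64, 64))
  expect_true(all(z == 0))
  freqs <- exp(seq(log(0.1), log(50), length.out = 64))
  for (f0 in c(1, 5, 20)) {
    img <- scalogram_image(sin(2 * pi * f0 * (0:1023) / 100), rate = 100)
    peak_row <- which.max(apply(img, 1, max))
    expect_lt(abs(log(freqs[peak_row] / f0)), log(1.35))
  }
})

test_that("GASF images match the direct double-loop computation", {
  v <- with_test_seed(28, stats::rnorm(64))
  g <- gasf_image(v)
  expect_equal(dim(g), c(64, 64))
  expect_equal(g, t(g))                      # cos symmetry
  expect_equal(g, bf_gasf(v), tolerance = 1e-12)
  expect_equal(gasf_image(rep(7, 64)), matrix(1, 64, 64))  # all at the max
  v2 <- with_test_seed(29, stats::rnorm(1024))
  expect_equal(gasf_image(v2), bf_gasf(v2), tolerance = 1e-12)
})

test_that("correlation-based selection keeps one representative per group", {
  with_test_seed(30, {
    x <- matrix(stats::rnorm(200 * 4), 200,
                dimnames = list(NULL, c("a", "b", "c", "d")))
    x <- cbind(x, a_copy = x[, "a"] * 2 + 1e-8 * stats::rnorm(200))
    sel <- correlation_select(x)
    expect_equal(sel$kept, c("a", "b", "c", "d"))
    expect_equal(sel$dropped, "a_copy")

    ortho <- matrix(stats::rnorm(500 * 8), 500,
                    dimnames = list(NULL, paste0("f", 1:8)))
    expect_equal(correlation_select(ortho)$kept, paste0("f", 1:8))

    const <- cbind(ortho[, 1:3], zv = rep(1, 500))
    expect_true("zv" %in% correlation_select(const)$kept)
  })
})

test_that("the documented drop-list reduces the 52 features to 24", {
  all52 <- names(wavelet_features(with_test_seed(31, stats::rnorm(1024))))
  dropped <- grepl("\\.(q05|q25|q50|q75|q95|var|rms)$", all52)
  expect_equal(sum(!dropped), 24)
  expect_setequal(all52[!dropped], wt_core_features())
  expect_length(wt_core_features(), 24)
})

test_that("feature extraction is deterministic and shape-lawful", {
  v <- with_test_seed(32, matrix(stats::rnorm(3 * 1024), 3))
  f1 <- segment_features(v, "stat_wt")
  f2 <- segment_features(v, "stat_wt")
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(3, 52))
  expect_equal(dim(segment_features(v, "stat_raw")), c(3, 13))
  expect_equal(dim(segment_features(v, "stat_ft")), c(3, 13))
  expect_equal(dim(segment_features(v, "gasf")), c(3, 64, 64))
  expect_equal(dim(segment_features(v, "spec")), c(3, 65, 65))
  expect_equal(dim(segment_features(v, "scalo")), c(3, 64, 64))
})
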