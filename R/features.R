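# Handcrafted statistical / complexity features and time-frequency images.

STAT_NAMES <- c("mean", "rms", "sd", "var", "skew",
                "q05", "q25", "q50", "q75", "q95",
                "zcr", "shannon_entropy", "perm_entropy")

#' Shannon entropy of a signal's energy distribution
#'
#' Treats the normalised squared magnitudes `p_i = v_i^2 / sum(v^2)` as a
#' probability distribution and returns its Shannon entropy in nats
#' (`0 * log 0 := 0`). An all-zero vector has entropy 0 (with a warning);
#' a uniform-magnitude vector of length n attains the maximum `log n`.
#'
#' @param v numeric vector.
#' @return scalar entropy in nats.
#' @export
shannon_entropy <- function(v) {
  if (length(v) == 0) stopf("empty input")
  e <- sum(v^2)
  if (e == 0) {
    warning("all-zero vector: Shannon entropy defined as 0", call. = FALSE)
    return(0)
  }
  p <- v^2 / e
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalised permutation entropy
#'
#' Slides an embedding window of `order` values (lag `delay`) along the
#' series, maps each window to its ordinal pattern (ties broken by index
#' order), and returns the Shannon entropy of the pattern distribution
#' normalised by `log(order!)` so the result lies in \[0, 1\]. A strictly
#' monotone series gives 0; long i.i.d. noise approaches 1.
#'
#' @param v numeric vector of length at least `order * delay + 1`.
#' @param order embedding dimension (default 3).
#' @param delay embedding lag (default 1).
#' @return scalar in \[0, 1\].
#' @export
permutation_entropy <- function(v, order = 3, delay = 1) {
  n <- length(v)
  if (n < order * delay + 1) stopf("input too short for permutation entropy")
  m <- n - (order - 1) * delay
  emb <- matrix(0, m, order)
  for (j in seq_len(order)) emb[, j] <- v[seq_len(m) + (j - 1) * delay]
  # rank of column j within its row, stable in index order
  code <- integer(m)
  for (j in seq_len(order)) {
    rj <- integer(m)
    for (k in seq_len(order)) {
      if (k == j) next
      rj <- rj + as.integer(emb[, k] < emb[, j] | (emb[, k] == emb[, j] & k < j))
    }
    code <- code + rj * order^(j - 1)
  }
  p <- tabulate(code + 1L, nbins = order^order)
  p <- p[p > 0] / m
  h <- -sum(p * log(p))
  h / log(factorial(order))
}

#' The 13 handcrafted statistical and complexity features
#'
#' Computes, in fixed order: mean, root mean square, standard deviation,
#' variance, skewness, the 0.05/0.25/0.5/0.75/0.95 quantiles, the
#' zero-crossing rate, Shannon entropy and normalised permutation entropy.
#' The zero-crossing rate is computed after mean-centering (normalised
#' signals live in \[0, 1\] and would otherwise never cross zero) as the
#' number of sign changes divided by `length - 1`. Standard deviation,
#' variance and skewness use the population (1/n) moments. A constant
#' input yields skewness 0 and entropies 0, with a warning.
#'
#' @param v numeric vector of length >= 4.
#' @param prefix optional name prefix (e.g. `"A3"`), producing names like
#'   `"A3.mean"`.
#' @return named numeric vector of length 13.
#' @export
stat_features <- function(v, prefix = NULL) {
  if (length(v) < 4) stopf("need at least 4 values")
  n <- length(v)
  mu <- mean(v)
  cent <- v - mu
  m2 <- mean(cent^2)
  sdv <- sqrt(m2)
  # treat numerically constant inputs (e.g. wavelet detail bands of a flat
  # signal, which are zero up to round-off) as degenerate
  constant <- (max(v) - min(v)) <= 1e-10 * max(1, abs(mu))
  if (constant) warning("constant input: skewness, ZCR and entropies set to 0",
                        call. = FALSE)
  skew <- if (constant) 0 else mean(cent^3) / sdv^3
  q <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  sgn <- cent >= 0
  zcr <- if (constant) 0 else sum(sgn[-1] != sgn[-n]) / (n - 1)
  se <- if (constant) 0 else suppressWarnings(shannon_entropy(v))
  pe <- if (constant) 0 else permutation_entropy(v)
  out <- c(mu, sqrt(mean(v^2)), sdv, m2, skew, q, zcr, se, pe)
  names(out) <- if (is.null(prefix)) STAT_NAMES else paste(prefix, STAT_NAMES, sep = ".")
  out
}

#' Magnitudes of the non-negative-frequency Fourier coefficients
#'
#' @param v numeric vector of even length `d`.
#' @return numeric vector of length `d/2 + 1` (bins 0 .. Nyquist).
#' @export
fourier_magnitude <- function(v) {
  d <- length(v)
  Mod(stats::fft(v))[seq_len(d %/% 2 + 1)]
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

#' Log-magnitude spectrogram image
#'
#' Short-time Fourier transform with a periodic Hann window of 128 samples,
#' hop 14 and no centering. For the default segment length `d = 1024` this
#' gives `(1024 - 128)/14 + 1 = 65` frames and `128/2 + 1 = 65` frequency
#' bins, i.e. a 65 x 65 image (rows = frequency, columns = time). Other
#' lengths are computed the same way and bilinearly resized to 65 x 65 with
#' a warning. Pixel values are `log10(max(|X|, 1e-10))`.
#'
#' @param v numeric segment.
#' @param window window length (default 128).
#' @param hop hop length in samples (default 14).
#' @return 65 x 65 numeric matrix.
#' @export
spectrogram_image <- function(v, window = 128, hop = 14) {
  d <- length(v)
  if (d < window) stopf("segment shorter than the analysis window")
  w <- hann_window(window)
  n_frames <- (d - window) %/% hop + 1L
  n_bins <- window %/% 2 + 1L
  img <- matrix(0, n_bins, n_frames)
  for (f in seq_len(n_frames)) {
    fr <- v[((f - 1) * hop + 1):((f - 1) * hop + window)] * w
    img[, f] <- Mod(stats::fft(fr))[seq_len(n_bins)]
  }
  img <- log10(pmax(img, 1e-10))
  if (n_bins != 65 || n_frames != 65) {
    warning(sprintf("spectrogram is %dx%d; resized to 65x65", n_bins, n_frames),
            call. = FALSE)
    img <- resize_matrix(img, 65, 65)
  }
  img
}

# Symlet-4 analysis/synthesis filter bank (standard 8-tap coefficients).
SYM4_DEC_LO <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
                 0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
                 -0.01260396726203783, 0.03222310060404270)
SYM4_DEC_HI <- c(-0.03222310060404270, -0.01260396726203783, 0.09921954357684722,
                 0.29785779560527736, -0.80373875180591614, 0.49761866763201545,
                 0.02963552764599851, -0.07576571478927333)

conv_full <- function(a, b) {
  la <- length(a); lb <- length(b); nn <- la + lb - 1
  Re(stats::fft(stats::fft(c(a, rep(0, lb - 1))) *
                stats::fft(c(b, rep(0, la - 1))), inverse = TRUE)) / nn
}

# One analysis step: symmetric (edge-repeated) extension, filter, decimate.
dwt_step <- function(x, lo = SYM4_DEC_LO, hi = SYM4_DEC_HI) {
  fl <- length(lo); n <- length(x)
  ext <- c(rev(x[seq_len(fl - 1)]), x, rev(x[seq(n - fl + 2, n)]))
  L <- (n + fl - 1) %/% 2
  idx <- seq(fl + 1, by = 2, length.out = L)
  list(a = conv_full(ext, lo)[idx], d = conv_full(ext, hi)[idx])
}

# One synthesis step, trimming to the target length n.
idwt_step <- function(a, d, n, lo = SYM4_DEC_LO, hi = SYM4_DEC_HI) {
  up <- function(v) { u <- numeric(2 * length(v)); u[seq(1, 2 * length(v), 2)] <- v; u }
  y <- conv_full(up(a), rev(lo)) + conv_full(up(d), rev(hi))
  fl <- length(lo)
  y[(fl - 1):(fl - 2 + n)]
}

#' Multi-resolution symlet-4 wavelet decomposition
#'
#' Three-level discrete wavelet transform with the symlet-4 filter bank and
#' symmetric signal extension. Returns the level-3 approximation and the
#' three detail bands; coefficient counts roughly halve per level (plus a
#' small filter overhang). The decomposition is exactly invertible via
#' [dwt_reconstruct()].
#'
#' @param v numeric vector of length >= 8.
#' @param levels number of decomposition levels (default 3).
#' @return named list `A3, D3, D2, D1` (for `levels = 3`) of coefficient
#'   vectors, plus an attribute `lengths` with the per-level input lengths.
#' @export
dwt_multires <- function(v, levels = 3) {
  if (length(v) < 8) stopf("need at least 8 samples for the symlet-4 transform")
  out <- list()
  lens <- integer(levels)
  x <- v
  for (l in seq_len(levels)) {
    lens[l] <- length(x)
    st <- dwt_step(x)
    out[[paste0("D", l)]] <- st$d
    x <- st$a
  }
  out[[paste0("A", levels)]] <- x
  out <- out[c(paste0("A", levels), paste0("D", seq(levels, 1)))]
  attr(out, "lengths") <- lens
  out
}

#' Reconstruct a signal from its wavelet bands
#'
#' Inverse of [dwt_multires()]; reconstruction is exact to numerical
#' round-off.
#'
#' @param bands output of [dwt_multires()].
#' @return numeric vector of the original length.
#' @export
dwt_reconstruct <- function(bands) {
  lens <- attr(bands, "lengths")
  levels <- length(lens)
  a <- bands[[paste0("A", levels)]]
  for (l in seq(levels, 1)) {
    a <- idwt_step(a, bands[[paste0("D", l)]], lens[l])
  }
  a
}

#' The 52 wavelet-domain handcrafted features
#'
#' Applies [stat_features()] to each of the four resolutions `A3, D3, D2,
#' D1` of the 3-level symlet-4 decomposition and concatenates them in that
#' order, giving 4 x 13 = 52 named features.
#'
#' @param v numeric segment (length >= 8).
#' @return named numeric vector of length 52.
#' @export
wavelet_features <- function(v) {
  b <- dwt_multires(v)
  unlist(lapply(names(b), function(nm) stat_features(b[[nm]], prefix = nm)))
}

#' Names of the 24 core wavelet features
#'
#' The documented feature-selection drop-list: within each of the four
#' wavelet resolutions, the five quantiles are strongly inter-correlated
#' and the variance and RMS duplicate the standard deviation, so those
#' seven statistics are dropped per resolution. What remains are the mean,
#' standard deviation, skewness, zero-crossing rate, Shannon entropy and
#' permutation entropy of A3, D3, D2 and D1 - 24 features in total.
#'
#' @return character vector of 24 feature names.
#' @export
wt_core_features <- function() {
  keep <- c("mean", "sd", "skew", "zcr", "shannon_entropy", "perm_entropy")
  as.vector(vapply(c("A3", "D3", "D2", "D1"),
                   function(r) paste(r, keep, sep = "."), character(6)))
}

#' Morlet scalogram image
#'
#' Continuous wavelet transform magnitude with an analytic Morlet wavelet
#' (centre frequency parameter 6) over 64 geometrically spaced scales
#' spanning pseudo-frequencies 0.1-50 Hz, computed in the frequency domain.
#' The time axis is block-averaged down to 64 columns, yielding a 64 x 64
#' image (rows = scales, ordered from low to high frequency).
#'
#' @param v numeric segment (default length 1024).
#' @param rate sampling rate in Hz used for the frequency grid (default 100).
#' @param n_scales number of scales (default 64).
#' @param freq_range pseudo-frequency span in Hz (default `c(0.1, 50)`).
#' @return 64 x 64 numeric matrix.
#' @export
scalogram_image <- function(v, rate = 100, n_scales = 64,
                            freq_range = c(0.1, 50)) {
  d <- length(v)
  w0 <- 6
  fc <- w0 / (2 * pi)
  freqs <- exp(seq(log(freq_range[1]), log(freq_range[2]), length.out = n_scales))
  scales <- fc * rate / freqs             # in samples
  xf <- stats::fft(v)
  omega <- 2 * pi * (seq_len(d) - 1) / d  # angular frequency grid (cycles/sample)
  omega[omega > pi] <- omega[omega > pi] - 2 * pi
  img <- matrix(0, n_scales, d)
  for (si in seq_len(n_scales)) {
    a <- scales[si]
    psi <- pi^(-0.25) * sqrt(2 * pi * a) * exp(-0.5 * (a * omega - w0)^2) * (omega > 0)
    img[si, ] <- Mod(stats::fft(xf * psi, inverse = TRUE)) / d
  }
  # block-average the time axis to 64 columns
  n_cols <- 64L
  edges <- floor(seq(0, d, length.out = n_cols + 1))
  out <- matrix(0, n_scales, n_cols)
  for (ci in seq_len(n_cols)) {
    cols <- (edges[ci] + 1):edges[ci + 1]
    out[, ci] <- rowMeans(img[, cols, drop = FALSE])
  }
  if (n_scales != 64) out <- resize_matrix(out, 64, 64)
  out
}

#' Gramian angular summation field image
#'
#' Downsamples the segment to 64 points by piecewise aggregate
#' approximation, rescales to \[-1, 1\], maps each value to a polar angle
#' `phi = arccos(x)`, and forms the 64 x 64 image
#' `G[i, j] = cos(phi_i + phi_j)`. The image is symmetric. A constant
#' segment rescales to its own maximum (all angles 0), giving an all-ones
#' image.
#'
#' @param v numeric segment of length >= 64.
#' @param size output size (default 64).
#' @return `size` x `size` numeric matrix.
#' @export
gasf_image <- function(v, size = 64) {
  d <- length(v)
  if (d < size) stopf("segment shorter than the target image size")
  edges <- floor(seq(0, d, length.out = size + 1))
  paa <- vapply(seq_len(size), function(i) mean(v[(edges[i] + 1):edges[i + 1]]),
                numeric(1))
  lo <- min(paa); hi <- max(paa)
  x <- if (hi == lo) rep(1, size) else 2 * (paa - lo) / (hi - lo) - 1
  x <- pmin(1, pmax(-1, x))
  s <- sqrt(pmax(0, 1 - x^2))
  outer(x, x) - outer(s, s)   # cos(phi_i + phi_j)
}

#' Drop highly correlated features
#'
#' Computes pairwise Pearson correlations, links features with `|r|`
#' exceeding the threshold, and keeps one representative per connected
#' group: the first in declared column order (so e.g. declaring the median
#' before the other quantiles keeps the median). Zero-variance columns
#' correlate with nothing and are kept standalone. The result is
#' deterministic.
#'
#' @param m numeric feature matrix with column names (>= 2 rows).
#' @param threshold absolute-correlation threshold (default 0.8).
#' @return list with `matrix` (reduced columns), `kept` and `dropped`
#'   (character vectors of names), and `groups` (list of correlated groups).
#' @export
correlation_select <- function(m, threshold = 0.8) {
  if (nrow(m) < 2) stopf("need at least 2 rows")
  p <- ncol(m)
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  r[!is.finite(r)] <- 0   # zero-variance columns: correlation defined as 0
  adj <- abs(r) > threshold
  diag(adj) <- FALSE
  comp <- integer(p)
  cur <- 0L
  for (v in seq_len(p)) {
    if (comp[v] != 0) next
    cur <- cur + 1L
    queue <- v
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      if (comp[u] != 0) next
      comp[u] <- cur
      queue <- c(queue, which(adj[u, ] & comp == 0))
    }
  }
  keep_idx <- vapply(seq_len(max(comp)), function(g) min(which(comp == g)),
                     integer(1))
  keep_idx <- sort(keep_idx)
  groups <- lapply(seq_len(max(comp)), function(g) colnames(m)[comp == g])
  list(matrix = m[, keep_idx, drop = FALSE],
       kept = colnames(m)[keep_idx],
       dropped = setdiff(colnames(m), colnames(m)[keep_idx]),
       groups = groups[vapply(groups, length, integer(1)) > 1])
}

#' Extract a feature matrix from a segment batch
#'
#' Applies the chosen representation to every row of a segment batch.
#' Vector representations give a numeric matrix (rows = segments); image
#' representations give a 3-D array (segments x rows x cols).
#'
#' @param x an `epg_segments` object or a plain matrix of segment rows.
#' @param kind one of `"stat_raw"` (13 features of the raw segment),
#'   `"stat_ft"` (13 features of the Fourier magnitude spectrum),
#'   `"stat_wt"` (52 wavelet-domain features), `"raw"` (the segment values
#'   themselves), `"gasf"`, `"spec"`, `"scalo"` (images).
#' @param rate sampling rate, used by the scalogram frequency grid.
#' @return matrix or 3-D array of features.
#' @export
segment_features <- function(x, kind = c("stat_wt", "stat_raw", "stat_ft",
                                         "raw", "gasf", "spec", "scalo"),
                             rate = 100) {
  kind <- match.arg(kind)
  vals <- if (inherits(x, "epg_segments")) x$values else x
  n <- nrow(vals)
  if (kind == "raw") return(vals)
  if (kind %in% c("stat_raw", "stat_ft", "stat_wt")) {
    fn <- switch(kind,
                 stat_raw = function(v) stat_features(v),
                 stat_ft = function(v) stat_features(fourier_magnitude(v)),
                 stat_wt = wavelet_features)
    first <- fn(vals[1, ])
    out <- matrix(0, n, length(first), dimnames = list(NULL, names(first)))
    out[1, ] <- first
    if (n > 1) for (i in 2:n) out[i, ] <- fn(vals[i, ])
    return(out)
  }
  fn <- switch(kind,
               gasf = function(v) gasf_image(v),
               spec = function(v) spectrogram_image(v),
               scalo = function(v) scalogram_image(v, rate = rate))
  first <- fn(vals[1, ])
  out <- array(0, dim = c(n, nrow(first), ncol(first)))
  out[1, , ] <- first
  if (n > 1) for (i in 2:n) out[i, , ] <- fn(vals[i, ])
  out
}
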