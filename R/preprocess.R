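#' Min-max normalise a recording
#'
#' Rescales the amplitude affinely so that the minimum maps to 0 and the
#' maximum to 1. A constant recording maps to all zeros with a warning.
#'
#' @param rec an [epg_recording()].
#' @return a normalised [epg_recording()].
#' @export
normalize_recording <- function(rec) {
  x <- rec$samples
  if (!all(is.finite(x))) stopf("recording contains non-finite values")
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    warning("constant recording: normalised to all zeros", call. = FALSE)
    rec$samples <- rep(0, length(x))
  } else {
    rec$samples <- (x - lo) / (hi - lo)
  }
  rec
}

#' Cut a recording into fixed-length segments
#'
#' Windows of length `d` start at timesteps `0, s, 2s, ...` (0-based). A
#' trailing window extending past the end of the recording is padded by
#' repeating the final available value, so with `s = d` every timestep
#' belongs to exactly one segment and an 8-hour 100 Hz recording yields
#' `ceiling(2880000 / 1024) = 2813` windows.
#'
#' @param rec an [epg_recording()].
#' @param d window length in samples (default 1024, i.e. 10.24 s at 100 Hz).
#' @param s stride in samples (default `d`: non-overlapping tiling).
#' @return an object of class `epg_segments`: list with `values` (matrix,
#'   one row per segment), `starts` (0-based start indices), `d`, `s`,
#'   `n_samples` (parent length) and `rate`.
#' @export
segment_recording <- function(rec, d = 1024, s = d) {
  if (d < 2) stopf("d must be >= 2")
  if (s < 1) stopf("s must be >= 1")
  n <- length(rec$samples)
  k <- max(1L, as.integer(ceiling(max(0, n - d) / s)) + 1L)
  starts <- (seq_len(k) - 1L) * s
  vals <- matrix(0, nrow = k, ncol = d)
  for (i in seq_len(k)) {
    lo <- starts[i] + 1L
    hi <- min(n, starts[i] + d)
    w <- rec$samples[lo:hi]
    if (length(w) < d) w <- c(w, rep(w[length(w)], d - length(w)))
    vals[i, ] <- w
  }
  structure(list(values = vals, starts = starts, d = as.integer(d),
                 s = as.integer(s), n_samples = n, rate = rec$rate),
            class = "epg_segments")
}

#' @export
print.epg_segments <- function(x, ...) {
  cat(sprintf("<epg_segments: %d windows of d=%d (stride %d) from %d samples>\n",
              nrow(x$values), x$d, x$s, x$n_samples))
  invisible(x)
}

#' Majority label of each segment
#'
#' Each segment receives the most frequent per-timestep ground-truth label
#' within its (unpadded) span; ties are broken by the canonical order
#' `NP < C < pd < E1 < E2 < F < G`.
#'
#' @param segs an `epg_segments` object.
#' @param truth per-timestep label factor covering the parent recording
#'   (e.g. from [track_to_labels()]).
#' @return factor of segment labels, one per row of `segs$values`.
#' @export
label_segments <- function(segs, truth) {
  if (length(truth) < segs$n_samples) {
    stopf("truth labels (%d) shorter than the recording (%d)",
          length(truth), segs$n_samples)
  }
  code <- as.integer(factor(as.character(truth), levels = EPG_LABELS))
  out <- integer(nrow(segs$values))
  for (i in seq_along(out)) {
    lo <- segs$starts[i] + 1L
    hi <- min(segs$n_samples, segs$starts[i] + segs$d)
    if (hi < lo) stopf("segment %d has no overlap with the recording", i)
    counts <- tabulate(code[lo:hi], nbins = 7L)
    out[i] <- which.max(counts)  # first maximum = canonical-order tie-break
  }
  factor(EPG_LABELS[out], levels = EPG_LABELS)
}

#' Pad a short waveform occurrence to a full-length window
#'
#' A waveform occupying samples `[i, j)` (0-based, `j - i < d`) is extended
#' symmetrically about its midpoint `m = floor((i + j) / 2)` by taking the
#' length-`d` window of the parent recording centred there. If the centred
#' window overruns a recording boundary it is shifted minimally to fit.
#'
#' @param rec an [epg_recording()] of at least `d` samples.
#' @param i,j 0-based half-open occurrence bounds in samples.
#' @param d target window length.
#' @return list with `values` (length `d`) and `start` (0-based window start
#'   in the parent recording).
#' @export
pad_sample <- function(rec, i, j, d = 1024) {
  n <- length(rec$samples)
  if (n < d) stopf("recording (%d samples) shorter than window d=%d", n, d)
  if (j - i >= d) {
    # occurrence already fills the window: centred crop, identity when == d
    start <- i + ((j - i) - d) %/% 2
  } else {
    m <- floor((i + j) / 2)
    start <- m - d %/% 2 + 1          # 0-based window start
  }
  start <- max(0L, min(start, n - d)) # minimal shift to fit
  list(values = rec$samples[(start + 1):(start + d)], start = as.integer(start))
}

#' Oversample a potential-drop occurrence
#'
#' pd events are rare and short, so each occurrence is expanded into
#' `2d/s + 1` overlapping training windows: starting from the double-width
#' context anchored at `m - d + 1` (`m` the occurrence midpoint), windows of
#' length `d` are taken at offsets `k * s` for `k = 0, ..., 2d/s`. Windows
#' are read from the parent recording and shifted minimally at recording
#' boundaries. With the defaults `d = 1024`, `s = 128` each pd yields 17
#' windows.
#'
#' @param rec an [epg_recording()].
#' @param i,j 0-based half-open occurrence bounds in samples.
#' @param d window length (default 1024).
#' @param s oversampling stride in samples (default 128, i.e. 1.28 s).
#' @return list of `2d/s + 1` windows, each as in [pad_sample()].
#' @export
oversample_pd <- function(rec, i, j, d = 1024, s = 128) {
  n <- length(rec$samples)
  if (n < d) stopf("recording (%d samples) shorter than window d=%d", n, d)
  if (s < 1) stopf("s must be >= 1")
  m <- floor((i + j) / 2)
  anchor <- m - d + 1
  k <- 0:((2 * d) %/% s)
  lapply(k, function(kk) {
    start <- anchor + kk * s
    start <- max(0L, min(start, n - d))
    list(values = rec$samples[(start + 1):(start + d)], start = as.integer(start))
  })
}

#' Specification of the data split
#'
#' @param holdout_fraction fraction of whole recordings reserved intact for
#'   whole-recording annotation tests (Subset 2); default 0.10.
#' @param train,val,test fractions of the segment database (Subset 1);
#'   defaults 0.70 / 0.10 / 0.20, must sum to 1.
#' @param seed integer seed for the holdout draw and segment shuffle.
#' @return object of class `epg_split_spec`.
#' @export
split_spec <- function(holdout_fraction = 0.10, train = 0.70, val = 0.10,
                       test = 0.20, seed = 1) {
  if (abs(train + val + test - 1) > 1e-9) stopf("train+val+test must sum to 1")
  if (any(c(train, val, test) <= 0) || any(c(train, val, test) >= 1)) {
    stopf("split fractions must lie in (0, 1)")
  }
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stopf("holdout_fraction must lie in (0, 1)")
  }
  structure(list(holdout_fraction = holdout_fraction, train = train,
                 val = val, test = test, seed = as.integer(seed)),
            class = "epg_split_spec")
}

#' Split a dataset into a segment database and held-out recordings
#'
#' Reserves about 10% of recordings (rounded, at least one) intact as
#' Subset 2. The remaining recordings are min-max normalised, cut into
#' non-overlapping segments of length `d`, labelled by majority vote,
#' shuffled with the given seed and divided 70/10/20 into train /
#' validation / test. pd occurrences of the training recordings are then
#' oversampled (stride `pd_stride`) and appended to the training portion
#' only, so the validation and test sets see no augmented windows.
#'
#' @param pairs list of `list(recording =, track =)` pairs, e.g. from
#'   [generate_dataset()]; at least 2 recordings.
#' @param spec an [split_spec()].
#' @param d segment length (default 1024).
#' @param pd_stride oversampling stride (default 128).
#' @param oversample logical; apply pd oversampling to the training split
#'   (default TRUE).
#' @return object of class `epg_split`: list with matrices/labels
#'   `train_x, train_y, val_x, val_y, test_x, test_y`, the held-out
#'   `holdout` pairs, and bookkeeping (`n_segments`, indices, `d`).
#' @export
split_dataset <- function(pairs, spec = split_spec(), d = 1024,
                          pd_stride = 128, oversample = TRUE) {
  n_rec <- length(pairs)
  if (n_rec < 2) stopf("need at least 2 recordings to split")
  with_seed(mix_seed(spec$seed, 11L), {
    n_hold <- max(1L, round(spec$holdout_fraction * n_rec))
    hold_idx <- sort(sample.int(n_rec, n_hold))
    sub1 <- setdiff(seq_len(n_rec), hold_idx)

    xs <- list(); ys <- list()
    pd_windows <- list(); pd_labels <- list()
    for (ri in sub1) {
      rec <- normalize_recording(pairs[[ri]]$recording)
      track <- pairs[[ri]]$track
      segs <- segment_recording(rec, d = d, s = d)
      truth <- track_to_labels(track, length(rec$samples), rec$rate)
      xs[[length(xs) + 1L]] <- segs$values
      ys[[length(ys) + 1L]] <- label_segments(segs, truth)
      if (oversample) {
        pd_rows <- which(as.character(track$label) == "pd")
        ends <- c(track$start_time[-1], track_end_time(track))
        for (pi in pd_rows) {
          i0 <- round(track$start_time[pi] * rec$rate)
          j0 <- round(ends[pi] * rec$rate)
          ws <- oversample_pd(rec, i0, j0, d = d, s = pd_stride)
          pd_windows[[length(pd_windows) + 1L]] <-
            do.call(rbind, lapply(ws, `[[`, "values"))
        }
      }
    }
    x <- do.call(rbind, xs)
    y <- factor(unlist(lapply(ys, as.character)), levels = EPG_LABELS)
    n_seg <- nrow(x)

    perm <- sample.int(n_seg)
    n_tr <- round(spec$train * n_seg)
    n_va <- round(spec$val * n_seg)
    tr <- perm[seq_len(n_tr)]
    va <- perm[n_tr + seq_len(n_va)]
    te <- perm[(n_tr + n_va + 1):n_seg]

    train_x <- x[tr, , drop = FALSE]; train_y <- y[tr]
    if (oversample && length(pd_windows) > 0) {
      aug <- do.call(rbind, pd_windows)
      train_x <- rbind(train_x, aug)
      train_y <- factor(c(as.character(train_y), rep("pd", nrow(aug))),
                        levels = EPG_LABELS)
    }
    structure(list(
      train_x = train_x, train_y = train_y,
      val_x = x[va, , drop = FALSE], val_y = y[va],
      test_x = x[te, , drop = FALSE], test_y = y[te],
      holdout = pairs[hold_idx],
      holdout_idx = hold_idx, n_segments = n_seg, d = as.integer(d)),
      class = "epg_split")
  })
}

#' @export
print.epg_split <- function(x, ...) {
  cat(sprintf(
    "<epg_split: %d/%d/%d train/val/test segments (d=%d), %d held-out recordings>\n",
    nrow(x$train_x), nrow(x$val_x), nrow(x$test_x), x$d, length(x$holdout)))
  invisible(x)
}
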