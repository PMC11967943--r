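# Independent brute-force reference implementations and small fixtures.
# These deliberately avoid the package's own code paths: sums are written
# out longhand so they can serve as oracles for the vectorised versions.

bf_stat_features <- function(v) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  q <- as.numeric(stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95)))
  cent <- v - mu
  crossings <- 0
  for (i in 2:n) {
    if ((cent[i] >= 0) != (cent[i - 1] >= 0)) crossings <- crossings + 1
  }
  c(mean = mu, rms = sqrt(sum(v^2) / n), sd = sqrt(m2), var = m2,
    skew = m3 / m2^1.5, q05 = q[1], q25 = q[2], q50 = q[3], q75 = q[4],
    q95 = q[5], zcr = crossings / (n - 1),
    shannon_entropy = bf_shannon(v), perm_entropy = bf_perm_entropy(v))
}

bf_shannon <- function(v) {
  p <- v^2 / sum(v^2)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi)
  h
}

# Pattern counting by explicit permutation lookup.
bf_perm_entropy <- function(v, order = 3, delay = 1) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  stopifnot(order == 3)
  m <- length(v) - (order - 1) * delay
  counts <- numeric(length(perms))
  for (i in seq_len(m)) {
    w <- v[c(i, i + delay, i + 2 * delay)]
    o <- order(w)  # ties broken by index order (stable)
    for (pi in seq_along(perms)) {
      if (all(o == perms[[pi]])) { counts[pi] <- counts[pi] + 1; break }
    }
  }
  p <- counts[counts > 0] / m
  h <- 0
  for (pi in p) h <- h - pi * log(pi)
  h / log(factorial(order))
}

bf_gasf <- function(v, size = 64) {
  d <- length(v)
  edges <- floor(seq(0, d, length.out = size + 1))
  paa <- numeric(size)
  for (i in seq_len(size)) paa[i] <- mean(v[(edges[i] + 1):edges[i + 1]])
  lo <- min(paa); hi <- max(paa)
  x <- if (hi == lo) rep(1, size) else 2 * (paa - lo) / (hi - lo) - 1
  phi <- acos(pmin(1, pmax(-1, x)))
  g <- matrix(0, size, size)
  for (i in seq_len(size)) for (j in seq_len(size)) g[i, j] <- cos(phi[i] + phi[j])
  g
}

# One-vs-rest TP/FP/FN tally from raw label vectors.
bf_metrics <- function(true, pred) {
  classes <- EPG_LABELS
  f1 <- recall <- setNames(numeric(7), classes)
  for (cl in classes) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    recall[cl] <- if (tp + fn == 0) NA else tp / (tp + fn)
    prec <- if (tp + fp == 0) NA else tp / (tp + fp)
    f1[cl] <- if (is.na(recall[cl])) NA
              else if (is.na(prec) || prec + recall[cl] == 0) 0
              else 2 * prec * recall[cl] / (prec + recall[cl])
  }
  present <- !is.na(recall)
  list(oa = sum(true == pred) / length(true),
       recall = recall, macro_f1 = mean(f1[present]))
}

# Independent grammar checker (distinct logic from count_grammar_violations):
# walks the label sequence with an explicit state flag.
bf_grammar_ok <- function(track) {
  labs <- as.character(track$label)
  probed <- FALSE
  for (i in seq_along(labs)) {
    l <- labs[i]
    if (l == "C") probed <- TRUE
    if (l %in% c("E1", "E2", "F", "G") && !probed) return(FALSE)
    if (l == "pd") {
      if (i == 1 || i == length(labs)) return(FALSE)
      if (labs[i - 1] != "C" || labs[i + 1] != "C") return(FALSE)
    }
  }
  TRUE
}

# Dominant periodogram frequency (mean-removed), in Hz.
bf_dominant_freq <- function(v, rate) {
  v <- v - mean(v)
  n <- length(v)
  mag <- Mod(stats::fft(v))[2:(n %/% 2 + 1)]
  which.max(mag) * rate / n
}

# A small deterministic recording with a grid-aligned two-class track.
toy_pair <- function(n = 4096, rate = 100, seed = 99) {
  rec <- with_test_seed(seed, epg_recording(stats::rnorm(n), rate = rate))
  track <- epg_track(c("NP", "C"), c(0, n / (2 * rate)), end_time = n / rate)
  list(recording = rec, track = track)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Finite-difference gradient check of a built network in training mode.
nn_gradcheck <- function(net, xin, y, npick = 3, eps = 1e-5) {
  loss_of <- function() {
    epgkit:::xent_loss(epgkit:::nn_forward_list(net, xin, TRUE), y)$loss
  }
  logits <- epgkit:::nn_forward_list(net, xin, training = TRUE)
  dy <- epgkit:::xent_loss(logits, y)$grad
  for (l in rev(net$layers)) dy <- epgkit:::layer_backward(l, dy)
  worst <- 0
  for (l in epgkit:::collect_layers(net$layers)) {
    params <- epgkit:::layer_params(l)
    # conv biases feeding a batch norm live in a null direction of the loss;
    # their true gradient is ~0 and relative error is meaningless there
    if (l$type == "conv") params <- setdiff(params, "b")
    for (p in params) {
      g <- switch(p, W = l$gW, b = l$gb, gamma = l$ggamma, beta = l$gbeta)
      if (is.null(g)) next
      v <- get(p, envir = l)
      rs <- if (l$type == "bn") list(m = l$run_mean, v = l$run_var)
      for (k in sample(length(v), min(npick, length(v)))) {
        v0 <- v[k]
        v[k] <- v0 + eps; assign(p, v, envir = l); lp <- loss_of()
        v[k] <- v0 - eps; assign(p, v, envir = l); lm <- loss_of()
        v[k] <- v0; assign(p, v, envir = l)
        num <- (lp - lm) / (2 * eps)
        worst <- max(worst, abs(num - g[k]) / max(1e-6, abs(num) + abs(g[k])))
      }
      if (l$type == "bn") {
        assign("run_mean", rs$m, envir = l)
        assign("run_var", rs$v, envir = l)
      }
    }
  }
  worst
}

# Two-class separable toy segments: distinct dominant frequencies.
toy_separable <- function(n_per_class = 40, d = 256, rate = 100, seed = 7) {
  with_test_seed(seed, {
    t <- (seq_len(d) - 1) / rate
    x <- rbind(
      t(replicate(n_per_class, sin(2 * pi * 2 * t + stats::runif(1, 0, 6)) +
                    stats::rnorm(d, 0, 0.1))),
      t(replicate(n_per_class, sin(2 * pi * 8 * t + stats::runif(1, 0, 6)) +
                    stats::rnorm(d, 0, 0.1))))
    y <- factor(rep(c("NP", "C"), each = n_per_class), levels = EPG_LABELS)
    list(x = x, y = y)
  })
}
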