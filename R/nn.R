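# Minimal seeded conv-net engine used by the three neural classifier
# families. Tensors are stored channel-first: 1-D activations as
# (channels, length, batch) arrays, 2-D activations as
# (channels, height*width, batch) with the spatial shape kept alongside.
# Layers are environments holding parameters, Adam moments and the
# forward cache; gradients are produced by explicit backward passes.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = e)
  e
}

he_init <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / ncol)), nrow, ncol)
}

# Gather-window index matrix: taps x n_out positions into a length-L axis.
window_idx <- function(L, taps_offsets, stride) {
  span <- max(taps_offsets) + 1L
  n_out <- (L - span) %/% stride + 1L
  if (n_out < 1) stopf("input too short for this layer (length %d, span %d)", L, span)
  starts <- (seq_len(n_out) - 1L) * stride + 1L
  outer(taps_offsets, starts, `+`)
}

layer_conv1d <- function(Cin, Cout, k, Lin, stride = 1L, dilation = 1L,
                         pad = 0L) {
  span <- (k - 1L) * dilation + 1L
  Lp <- Lin + 2L * pad
  idx <- window_idx(Lp, (0:(k - 1L)) * dilation, stride)
  new_layer("conv", W = he_init(Cout, Cin * k), b = numeric(Cout),
            Cin = Cin, Cout = Cout, taps = k, idx = idx, pad = pad,
            Lin = Lin, Lp = Lp, Lout = ncol(idx), spatial_out = ncol(idx))
}

layer_conv2d <- function(Cin, Cout, k, Hin, Win, stride = 1L) {
  # valid convolution, square kernel
  Hout <- (Hin - k) %/% stride + 1L
  Wout <- (Win - k) %/% stride + 1L
  hi <- (seq_len(Hout) - 1L) * stride + 1L
  wi <- (seq_len(Wout) - 1L) * stride + 1L
  taps <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hin, `+`))  # k*k offsets
  starts <- as.vector(outer(hi, (wi - 1L) * Hin, `+`))
  idx <- outer(taps, starts, `+`)
  new_layer("conv", W = he_init(Cout, Cin * k * k), b = numeric(Cout),
            Cin = Cin, Cout = Cout, taps = k * k, idx = idx, pad = 0L,
            Lin = Hin * Win, Lp = Hin * Win, Lout = ncol(idx),
            Hout = Hout, Wout = Wout, spatial_out = ncol(idx))
}

layer_pool <- function(C, L, idx) {
  new_layer("pool", C = C, Lin = L, idx = idx, Lout = ncol(idx),
            spatial_out = ncol(idx))
}

layer_pool1d <- function(C, L, size = 3L, stride = size) {
  layer_pool(C, L, window_idx(L, 0:(size - 1L), stride))
}

layer_pool2d <- function(C, Hin, Win, size = 2L, stride = size) {
  Hout <- (Hin - size) %/% stride + 1L
  Wout <- (Win - size) %/% stride + 1L
  hi <- (seq_len(Hout) - 1L) * stride + 1L
  wi <- (seq_len(Wout) - 1L) * stride + 1L
  taps <- as.vector(outer(0:(size - 1L), (0:(size - 1L)) * Hin, `+`))
  starts <- as.vector(outer(hi, (wi - 1L) * Hin, `+`))
  l <- layer_pool(C, Hin * Win, outer(taps, starts, `+`))
  l$Hout <- Hout; l$Wout <- Wout
  l
}

layer_bn <- function(C) {
  new_layer("bn", gamma = rep(1, C), beta = numeric(C),
            run_mean = numeric(C), run_var = rep(1, C),
            momentum = 0.1, eps = 1e-5, C = C)
}

layer_relu <- function() new_layer("relu")
layer_flatten <- function() new_layer("flatten")
layer_dropout <- function(p = 0.5) new_layer("dropout", p = p)
layer_dense <- function(Fin, Fout) {
  new_layer("dense", W = he_init(Fout, Fin), b = numeric(Fout))
}

gather_cols <- function(x, idx, C, B) {
  cols <- x[, as.vector(idx), , drop = FALSE]
  dim(cols) <- c(C * nrow(idx), ncol(idx) * B)
  cols
}

layer_forward <- function(l, x, training) {
  switch(l$type,
    conv = {
      dims <- dim(x); C <- dims[1]; B <- dims[3]
      if (l$pad > 0) {
        xp <- array(0, c(C, l$Lp, B))
        xp[, (l$pad + 1):(l$pad + dims[2]), ] <- x
        x <- xp
      }
      M <- gather_cols(x, l$idx, C, B)
      y <- l$W %*% M + l$b
      dim(y) <- c(l$Cout, l$Lout, B)
      l$cache <- list(M = M, B = B, C = C)
      y
    },
    bn = {
      B <- dim(x)[3]
      if (training) {
        mu <- rowMeans(x, dims = 1)
        xc <- x - mu
        v <- rowMeans(xc^2, dims = 1)
        l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
        l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
      } else {
        mu <- l$run_mean
        xc <- x - mu
        v <- l$run_var
      }
      invstd <- 1 / sqrt(v + l$eps)
      xhat <- xc * invstd
      l$cache <- list(xhat = xhat, invstd = invstd, m = prod(dim(x)[-1]),
                      training = training)
      l$gamma * xhat + l$beta
    },
    relu = {
      l$cache <- x > 0
      x * l$cache
    },
    pool = {
      dims <- dim(x); C <- dims[1]; B <- dims[3]
      taps <- nrow(l$idx); n_out <- ncol(l$idx)
      cols <- x[, as.vector(l$idx), , drop = FALSE]
      dim(cols) <- c(C, taps, n_out, B)
      m <- cols[, 1, , , drop = FALSE]
      dim(m) <- c(C, n_out, B)
      amax <- array(1L, c(C, n_out, B))
      for (s in seq_len(taps)[-1]) {
        cs <- cols[, s, , , drop = FALSE]
        dim(cs) <- c(C, n_out, B)
        upd <- cs > m
        m[upd] <- cs[upd]
        amax[upd] <- s
      }
      l$cache <- list(amax = amax, C = C, B = B, L = dims[2])
      m
    },
    flatten = {
      l$cache <- dim(x)
      dim(x) <- c(prod(dim(x)[-length(dim(x))]), dim(x)[length(dim(x))])
      x
    },
    dropout = {
      if (training && l$p > 0) {
        mask <- (stats::runif(length(x)) > l$p) / (1 - l$p)
        dim(mask) <- dim(x)
        l$cache <- mask
        x * mask
      } else {
        l$cache <- NULL
        x
      }
    },
    dense = {
      l$cache <- x
      l$W %*% x + l$b
    },
    resblock = {
      l$x_in <- x
      h <- layer_forward(l$conv1, x, training)
      h <- layer_forward(l$relu1, h, training)
      h <- layer_forward(l$conv2, h, training)
      h <- layer_forward(l$relu2, h, training)
      h <- layer_forward(l$conv3, h, training)
      s <- if (is.null(l$proj)) x else layer_forward(l$proj, x, training)
      layer_forward(l$bn, h + s, training)
    },
    stopf("unknown layer type '%s'", l$type))
}

scatter_add <- function(dM, idx, C, L, B) {
  # dM: (C, taps, n_out, B) gradient of gathered windows -> (C, L, B)
  dx <- array(0, c(C, L, B))
  for (tt in seq_len(nrow(idx))) {
    pos <- idx[tt, ]
    slice <- dM[, tt, , , drop = FALSE]
    dim(slice) <- c(C, ncol(idx), B)
    dx[, pos, ] <- dx[, pos, , drop = FALSE] + slice
  }
  dx
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv = {
      B <- l$cache$B; C <- l$cache$C
      dim(dy) <- c(l$Cout, l$Lout * B)
      l$gW <- dy %*% t(l$cache$M)
      l$gb <- rowSums(dy)
      dM <- crossprod(l$W, dy)
      dim(dM) <- c(C, l$taps, l$Lout, B)
      dx <- scatter_add(dM, l$idx, C, l$Lp, B)
      if (l$pad > 0) dx <- dx[, (l$pad + 1):(l$Lp - l$pad), , drop = FALSE]
      dx
    },
    bn = {
      xhat <- l$cache$xhat; m <- l$cache$m
      l$ggamma <- rowSums(dy * xhat, dims = 1)
      l$gbeta <- rowSums(dy, dims = 1)
      dxhat <- dy * l$gamma
      if (!l$cache$training) {
        # eval mode: running stats are constants
        dxhat * l$cache$invstd
      } else {
        s1 <- rowSums(dxhat, dims = 1)
        s2 <- rowSums(dxhat * xhat, dims = 1)
        (l$cache$invstd / m) * (m * dxhat - s1 - xhat * s2)
      }
    },
    relu = dy * l$cache,
    pool = {
      c_ <- l$cache
      amax <- c_$amax
      oi <- slice.index(amax, 2)
      src <- l$idx[cbind(as.vector(amax), as.vector(oi))]
      lin <- as.vector(slice.index(amax, 1)) +
        (src - 1) * c_$C +
        (as.vector(slice.index(amax, 3)) - 1) * c_$C * c_$L
      dx <- array(0, c(c_$C, c_$L, c_$B))
      dx[lin] <- dx[lin] + as.vector(dy)
      dx
    },
    flatten = { dim(dy) <- l$cache; dy },
    dropout = if (is.null(l$cache)) dy else dy * l$cache,
    dense = {
      l$gW <- dy %*% t(l$cache)
      l$gb <- rowSums(dy)
      crossprod(l$W, dy)
    },
    resblock = {
      dh <- layer_backward(l$bn, dy)
      ds <- if (is.null(l$proj)) dh else layer_backward(l$proj, dh)
      d3 <- layer_backward(l$conv3, dh)
      d3 <- layer_backward(l$relu2, d3)
      d3 <- layer_backward(l$conv2, d3)
      d3 <- layer_backward(l$relu1, d3)
      d3 <- layer_backward(l$conv1, d3)
      d3 + ds
    },
    stopf("unknown layer type '%s'", l$type))
}

layer_params <- function(l) {
  switch(l$type,
    conv = , dense = c("W", "b"),
    bn = c("gamma", "beta"),
    character(0))
}

collect_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "resblock") {
      out <- c(out, list(l$conv1, l$conv2, l$conv3),
               if (!is.null(l$proj)) list(l$proj), list(l$bn))
    } else {
      out <- c(out, list(l))
    }
  }
  out
}

nn_count_params <- function(net) {
  sum(vapply(collect_layers(net$layers), function(l) {
    sum(vapply(layer_params(l), function(p) length(get(p, envir = l)),
               numeric(1)))
  }, numeric(1)))
}

adam_step <- function(net, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in collect_layers(net$layers)) {
    for (p in layer_params(l)) {
      g <- get(paste0("g", sub("W", "W", p)), envir = l)
      g <- switch(p, W = l$gW, b = l$gb, gamma = l$ggamma, beta = l$gbeta)
      if (is.null(g)) next
      mslot <- paste0("m_", p); vslot <- paste0("v_", p)
      m <- if (exists(mslot, envir = l)) get(mslot, envir = l) else 0 * g
      v <- if (exists(vslot, envir = l)) get(vslot, envir = l) else 0 * g
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      assign(mslot, m, envir = l)
      assign(vslot, v, envir = l)
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      assign(p, get(p, envir = l) - lr * mh / (sqrt(vh) + eps), envir = l)
    }
  }
}

nn_forward <- function(net, x, training = FALSE) {
  for (l in net$layers) x <- layer_forward(l, x, training)
  x
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Cross-entropy loss and logit gradient for integer labels y in 1..K.
xent_loss <- function(logits, y) {
  p <- softmax_cols(logits)
  B <- ncol(p)
  picked <- p[cbind(y, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  d <- p
  d[cbind(y, seq_len(B))] <- d[cbind(y, seq_len(B))] - 1
  list(loss = loss, grad = d / B)
}

# Convert user-facing batches to the internal channel-first layout.
to_internal <- function(x, input) {
  if (input == "1d") {
    if (!is.matrix(x)) stopf("1-D models expect a numeric matrix (segments x d)")
    aperm(array(x, c(nrow(x), 1, ncol(x))), c(2, 3, 1))
  } else {
    if (length(dim(x)) != 3) stopf("2-D models expect an array (segments x rows x cols)")
    # (B, H, W) -> (1, H*W, B) with column-major spatial flattening
    B <- dim(x)[1]
    out <- aperm(x, c(2, 3, 1))
    dim(out) <- c(1, dim(x)[2] * dim(x)[3], B)
    out
  }
}
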