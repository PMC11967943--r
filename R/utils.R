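# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific seed from a master seed; keeps results < 2^31.
mix_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 131) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Bilinear resize of a numeric matrix to nr x nc (used when image inputs
# arrive at a non-default segment length).
resize_matrix <- function(m, nr, nc) {
  if (nrow(m) == nr && ncol(m) == nc) return(m)
  ri <- seq(1, nrow(m), length.out = nr)
  ci <- seq(1, ncol(m), length.out = nc)
  r0 <- pmin(floor(ri), nrow(m) - 1L); r0[nrow(m) == 1] <- 1
  c0 <- pmin(floor(ci), ncol(m) - 1L); c0[ncol(m) == 1] <- 1
  if (nrow(m) == 1) r0 <- rep(1, nr)
  if (ncol(m) == 1) c0 <- rep(1, nc)
  fr <- ri - r0
  fc <- ci - c0
  r1 <- pmin(r0 + 1, nrow(m))
  c1 <- pmin(c0 + 1, ncol(m))
  top <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[r0, c1, drop = FALSE] * outer(1 - fr, fc)
  bot <- m[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    m[r1, c1, drop = FALSE] * outer(fr, fc)
  top + bot
}
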