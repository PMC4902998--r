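# internal numerics shared across modules

# reflect-pad a matrix by `pad` pixels on every side (no edge duplication,
# i.e. "symmetric" about the pixel centers is NOT used; we mirror about the
# edge so that pad 1 repeats row 2, matching scipy's 'reflect'/np.pad default
# would duplicate -- here we use whole-sample symmetric reflection, which for
# the small windows involved differs from alternatives only at the very rim)
pad_reflect <- function(m, pad) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(pad < nr, pad < nc)
  ri <- c(rev(seq_len(pad) + 1L), seq_len(nr), nr - seq_len(pad))
  ci <- c(rev(seq_len(pad) + 1L), seq_len(nc), nc - seq_len(pad))
  m[ri, ci, drop = FALSE]
}

# moving-window sum over an odd window, reflect padding, via integral image
box_sum <- function(m, window) {
  stopifnot(window %% 2 == 1, window >= 1)
  if (window == 1) return(m)
  pad <- (window - 1L) %/% 2L
  p <- pad_reflect(m, pad)
  # integral image with a zero first row/col
  ii <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  ii[-1L, -1L] <- t(apply(apply(p, 2L, cumsum), 1L, cumsum))
  nr <- nrow(m); nc <- ncol(m)
  r0 <- seq_len(nr); c0 <- seq_len(nc)
  ii[r0 + window, c0 + window, drop = FALSE] -
    ii[r0, c0 + window, drop = FALSE] -
    ii[r0 + window, c0, drop = FALSE] +
    ii[r0, c0, drop = FALSE]
}

clamp01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

# rasterized disc structuring element: offsets with euclidean norm <= radius
disc_kernel <- function(radius) {
  r <- max(0, radius)
  n <- as.integer(floor(r))
  off <- seq.int(-n, n)
  d <- sqrt(outer(off^2, off^2, "+"))
  matrix(as.numeric(d <= r + 1e-9), 2L * n + 1L, 2L * n + 1L)
}

# binary dilation with a disc of the given radius (radius 0 = identity)
dilate_disc <- function(mask, radius) {
  storage.mode(mask) <- "logical"
  if (radius <= 0 || !any(mask)) return(mask)
  k <- disc_kernel(radius)
  if (nrow(k) == 1L) return(mask)
  out <- EBImage::dilate(mask * 1, k)
  matrix(out > 0.5, nrow(mask), ncol(mask))
}

# 0-based row-major pixel index used for all deterministic tie-breaks
rowmajor_index <- function(rc0, width) {
  rc0[, 1L] * width + rc0[, 2L]
}

# run expr with a locally-seeded RNG, restoring the caller's state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
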