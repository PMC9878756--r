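# Small vectorized raster helpers: shift-based convolution, separable
# Gaussian smoothing with replicate padding, and 1-D grayscale morphology.
# Kept in base R so the row/col orientation contract is explicit.

# out[r, c] = m[r + dr, c + dc], zero outside.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
  if (r1 <= r2 && c1 <= c2)
    out[r1:r2, c1:c2] <- m[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  out
}

# Replicate-pad by pr rows / pc cols on each side.
pad_replicate <- function(m, pr, pc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, pr), seq_len(nr), rep(nr, pr))
  ci <- c(rep(1L, pc), seq_len(nc), rep(nc, pc))
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian smoothing, edge-replicated borders.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  p <- pad_replicate(m, r, r)
  tmp <- matrix(0, nrow(p), ncol(p))
  for (k in seq_along(w)) tmp <- tmp + w[k] * shift_mat(p, k - r - 1L, 0L)
  out <- matrix(0, nrow(p), ncol(p))
  for (k in seq_along(w)) out <- out + w[k] * shift_mat(tmp, 0L, k - r - 1L)
  out[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m)), drop = FALSE]
}

# Cross-correlation with an arbitrary kernel, zero-padded, anchored at the
# kernel element (anchor_r, anchor_c) (1-based).
cross_correlate <- function(m, kernel,
                            anchor_r = floor(nrow(kernel) / 2) + 1L,
                            anchor_c = floor(ncol(kernel) / 2) + 1L) {
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      k <- kernel[i, j]
      if (k != 0) out <- out + k * shift_mat(m, i - anchor_r, j - anchor_c)
    }
  }
  out
}

# Running min/max over a vertical window of `len` rows (centered), with
# replicate borders so structures touching the frame are not eroded away.
run_extreme_rows <- function(m, len, fun) {
  half_lo <- (len - 1L) %/% 2L
  half_hi <- len - 1L - half_lo
  p <- pad_replicate(m, max(half_lo, half_hi), 0L)
  acc <- NULL
  for (dr in (-half_lo):half_hi) {
    s <- shift_mat(p, dr, 0L)
    acc <- if (is.null(acc)) s else fun(acc, s)
  }
  pr <- max(half_lo, half_hi)
  acc[(pr + 1):(pr + nrow(m)), , drop = FALSE]
}

# Grayscale opening with a vertical line structuring element.
open_gray_vline <- function(m, len) {
  eroded <- run_extreme_rows(m, len, pmin)
  run_extreme_rows(eroded, len, pmax)
}
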