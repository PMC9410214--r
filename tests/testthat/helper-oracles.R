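# Independent brute-force oracles and fixture builders shared across tests.
# Oracles are deliberately written as plain nested loops so they share no
# code path with the implementation they check.

rand_gray <- function(h, w, seed) {
  withr::with_seed(seed, matrix(sample(0:255, h * w, replace = TRUE), h, w))
}

rand_rgb <- function(h, w, seed) {
  withr::with_seed(seed,
                   array(sample(0:255, h * w * 3, replace = TRUE),
                         c(h, w, 3)))
}

# random RGB scene whose dark channel is exactly zero in every patch of the
# given size: one channel is zeroed on a grid finer than the patch
dcp_zero_rgb <- function(h, w, seed, patch = 15L) {
  img <- rand_rgb(h, w, seed)
  step <- (patch - 1L) %/% 2L + 1L   # guarantees one zero per window
  rows <- seq(1L, h, by = step)
  cols <- seq(1L, w, by = step)
  img[rows, cols, 1] <- 0
  img
}

# nested-loop dark channel: min over in-bounds window and channels
oracle_dark_channel <- function(img, patch) {
  r <- (patch - 1L) %/% 2L
  h <- dim(img)[1]; w <- dim(img)[2]
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      m <- Inf
      for (di in -r:r) for (dj in -r:r) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
          for (c in 1:3) m <- min(m, img[ii, jj, c])
      }
      out[i, j] <- m
    }
  }
  out
}

# nested-loop single-stride 3x3 correlation for interior pixels only
oracle_filter_interior <- function(img, weights, cff, rounding) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, h, w)
  for (i in 2:(h - 1)) {
    for (j in 2:(w - 1)) {
      s <- 0
      for (p in 1:3) for (q in 1:3)
        s <- s + weights[p, q] * img[i + p - 2, j + q - 2]
      v <- switch(rounding,
                  floor = floor(s / cff),
                  half_up = floor(s / cff + 0.5),
                  ceil = ceiling(s / cff))
      out[i, j] <- min(max(v, 0), 255)
    }
  }
  out
}

# nested-loop blockwise EME
oracle_eme <- function(img, bh, bw, eps) {
  k1 <- ceiling(nrow(img) / bh); k2 <- ceiling(ncol(img) / bw)
  acc <- 0
  for (bi in 1:k1) for (bj in 1:k2) {
    blk <- img[((bi - 1) * bh + 1):min(bi * bh, nrow(img)),
               ((bj - 1) * bw + 1):min(bj * bw, ncol(img))]
    acc <- acc + 20 * log10((max(blk) + eps) / (min(blk) + eps))
  }
  acc / (k1 * k2)
}
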