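## Image quality measures used to evaluate the enhancement chain, plus the
## classical comparator filters (histogram equalization, 3x3 mean, adaptive
## Wiener) and transform-domain alpha rooting.

PSNR_CAP_DB <- 100 # reported instead of +Inf when MSE = 0, keeps CSVs numeric

check_pair <- function(original, result) {
  assert_gray(original)
  assert_gray(result)
  if (!identical(dim(original), dim(result)))
    stop("original and result must have identical dimensions", call. = FALSE)
}

#' Full-reference error metrics
#'
#' For a reference image `O` and a test image `R` of identical size:
#' * `mse`  — mean squared difference,
#' * `psnr` — `10 log10(255^2 / mse)` in dB, capped at 100 dB when `mse = 0`,
#' * `mae`  — mean absolute difference,
#' * `nae`  — `sum(|O - R|) / sum(O)` (normalized absolute error),
#' * `ncc`  — `sum(O * R) / sum(O^2)` (normalized cross-correlation,
#'   normalized by the reference's energy).
#'
#' @param original,result grayscale matrices of identical dimensions.
#' @return named list with components `mse`, `psnr`, `mae`, `nae`, `ncc`.
#' @export
error_metrics <- function(original, result) {
  check_pair(original, result)
  d <- original - result
  mse <- mean(d^2)
  psnr <- if (mse == 0) PSNR_CAP_DB else min(10 * log10(255^2 / mse),
                                             PSNR_CAP_DB)
  mae <- mean(abs(d))
  if (sum(original) == 0)
    stop("NAE/NCC undefined for an all-zero reference image", call. = FALSE)
  list(mse = mse, psnr = psnr, mae = mae,
       nae = sum(abs(d)) / sum(original),
       ncc = sum(original * result) / sum(original^2))
}

## separable 2-D convolution with a symmetric 1-D kernel, reflect border
conv_sep <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  p <- pad_matrix(m, r, "reflect")
  tmp <- matrix(0, h + 2 * r, w)
  for (i in seq_along(k))
    tmp <- tmp + k[i] * p[, i:(w + i - 1L), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k))
    out <- out + k[i] * tmp[i:(h + i - 1L), , drop = FALSE]
  out
}

gaussian_taps <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Structural similarity index (SSIM)
#'
#' Mean of the local SSIM map computed in sliding Gaussian windows
#' (default 11 x 11, sigma 1.5) with the standard stabilizers
#' `C1 = (0.01 * 255)^2`, `C2 = (0.03 * 255)^2`. Symmetric in its two
#' arguments and equal to 1 exactly when the images are identical.
#'
#' @param original,result grayscale matrices of identical dimensions, at
#'   least as large as the window.
#' @param window odd window edge length.
#' @param sigma Gaussian window standard deviation in pixels.
#' @return SSIM value in \[-1, 1\].
#' @export
ssim <- function(original, result, window = 11L, sigma = 1.5) {
  check_pair(original, result)
  if (min(dim(original)) < window)
    stop("images must be at least the SSIM window size", call. = FALSE)
  k <- gaussian_taps(sigma, (as.integer(window) - 1L) %/% 2L)
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  mu_x <- conv_sep(original, k); mu_y <- conv_sep(result, k)
  sxx <- conv_sep(original^2, k) - mu_x^2
  syy <- conv_sep(result^2, k) - mu_y^2
  sxy <- conv_sep(original * result, k) - mu_x * mu_y
  map <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  mean(map)
}

#' Shannon entropy of an 8-bit image
#'
#' Base-2 entropy of the 256-bin intensity histogram; 0 for a constant
#' image, 8 for a uniform occupation of all levels.
#'
#' @param img grayscale matrix.
#' @return entropy in bits, in \[0, 8\].
#' @export
img_entropy <- function(img) {
  assert_gray(img)
  p <- tabulate(round_half_up(img) + 1L, nbins = 256L)
  p <- p[p > 0] / length(img)
  -sum(p * log2(p))
}

#' Blockwise measure of enhancement (EME)
#'
#' Splits the image into `block_h` x `block_w` pixel blocks (trailing
#' partial blocks included) and averages `20 log10((Imax + eps) /
#' (Imin + eps))` over blocks, where `Imax`/`Imin` are the block extrema.
#' A no-reference contrast measure: 0 for a constant image, larger for
#' higher within-block dynamic range.
#'
#' @param img grayscale matrix.
#' @param block_h,block_w block size in pixels (default 8 x 8).
#' @param eps stabilizer guarding `Imin = 0`.
#' @return nonnegative EME value.
#' @export
eme <- function(img, block_h = 8L, block_w = 8L, eps = 1e-4) {
  assert_gray(img)
  block_h <- as.integer(block_h); block_w <- as.integer(block_w)
  if (block_h < 1L || block_w < 1L) stop("block size must be >= 1",
                                         call. = FALSE)
  k1 <- ceiling(nrow(img) / block_h)
  k2 <- ceiling(ncol(img) / block_w)
  total <- 0
  for (bi in seq_len(k1)) {
    rows <- ((bi - 1L) * block_h + 1L):min(bi * block_h, nrow(img))
    for (bj in seq_len(k2)) {
      cols <- ((bj - 1L) * block_w + 1L):min(bj * block_w, ncol(img))
      blk <- img[rows, cols]
      total <- total + 20 * log10((max(blk) + eps) / (min(blk) + eps))
    }
  }
  total / (k1 * k2)
}

#' Alpha rooting enhancement
#'
#' Transform-domain enhancement: each 2-D DFT magnitude is replaced by its
#' alpha-th root, normalized so the DC component (mean intensity) is
#' preserved — `F' = F (|F| / |F_DC|)^(1/alpha - 1)` — with phase kept, the
#' spectrum inverse-transformed, and the real part mapped back to
#' \[0, 255\] (min-max rescaled only if it leaves the 8-bit range, so
#' `alpha = 1` is an exact identity). Values of `alpha` below 1 attenuate
#' the non-DC spectrum (flattening the image, lowering its EME); values
#' above 1 boost it, so blockwise contrast grows monotonically with
#' `alpha` — the behavior reported for this enhancement family.
#'
#' @param img grayscale matrix.
#' @param alpha positive root parameter in (0, 1.5]; 1 is the identity.
#' @return enhanced grayscale matrix, same dimensions.
#' @export
alpha_rooting <- function(img, alpha) {
  assert_gray(img)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("alpha must be a positive number", call. = FALSE)
  f <- stats::fft(img)
  mag <- Mod(f)
  dc <- mag[1, 1]
  if (dc == 0) dc <- 1 # all-zero image: nothing to normalize
  fac <- ifelse(mag > 0, (mag / dc)^(1 / alpha - 1), 0)
  out <- Re(stats::fft(f * fac, inverse = TRUE)) / length(img)
  lo <- min(out); hi <- max(out)
  if (lo < -1e-9 || hi > 255 + 1e-9) {
    if (hi > lo) out <- (out - lo) / (hi - lo) * 255 else out <- out * 0
  }
  clip8(out)
}

#' Classical comparator filters
#'
#' The three reference enhancement/denoising methods the hexagonal filter
#' is compared against:
#' * `histogram_equalization` — global CDF remapping of the 256-level
#'   histogram;
#' * `mean3x3` — 3x3 box average (the square-lattice mean filter);
#' * `wiener3x3` — locally adaptive Wiener filter with 3x3 neighborhoods
#'   and the noise variance estimated as the mean local variance.
#'
#' @param img grayscale matrix.
#' @param name filter name.
#' @param config border/rounding contract used by `mean3x3`
#'   (see [filter_config()]).
#' @return filtered grayscale matrix, same dimensions.
#' @export
apply_reference_filter <- function(img,
                                   name = c("histogram_equalization",
                                            "mean3x3", "wiener3x3"),
                                   config = filter_config()) {
  name <- match.arg(name)
  assert_gray(img, 3L)
  switch(name,
    histogram_equalization = {
      v <- round_half_up(img)
      counts <- tabulate(v + 1L, nbins = 256L)
      cdf <- cumsum(counts)
      cdf_min <- min(cdf[cdf > 0])
      n <- length(img)
      if (n == cdf_min) return(img) # constant image: nothing to equalize
      lut <- round_half_up((cdf - cdf_min) / (n - cdf_min) * 255)
      matrix(lut[v + 1L], nrow(img), ncol(img))
    },
    mean3x3 = filter_image(img, matrix(1L, 3, 3), config),
    wiener3x3 = {
      box <- function(m) conv_box3(m)
      mu <- box(img)
      vr <- pmax(box(img^2) - mu^2, 0)
      noise <- mean(vr)
      gain <- ifelse(vr > noise, (vr - noise) / vr, 0)
      clip8(mu + gain * (img - mu))
    })
}

## 3x3 box mean with replicate border, floating point (no rounding)
conv_box3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- pad_matrix(m, 1L, "replicate")
  s <- matrix(0, h, w)
  for (dr in 0:2)
    for (dc in 0:2)
      s <- s + p[(1 + dr):(h + dr), (1 + dc):(w + dc), drop = FALSE]
  s / 9
}

#' Quality report for an image pair
#'
#' Bundles every metric in the evaluation protocol for one
#' (reference, test) pair: MSE, PSNR, SSIM, NCC, NAE, MAE, plus the
#' no-reference entropy and EME of the test image.
#'
#' @inheritParams error_metrics
#' @param eme_block EME block edge length in pixels.
#' @return an object of class `metric_report` (a named list of scalars).
#' @export
quality_report <- function(original, result, eme_block = 8L) {
  em <- error_metrics(original, result)
  structure(c(em, list(ssim = ssim(original, result),
                       entropy = img_entropy(result),
                       eme = eme(result, eme_block, eme_block))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("quality metrics:\n")
  for (nm in names(x))
    cat(sprintf("  %-8s %.6g\n", nm, x[[nm]]))
  invisible(x)
}
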