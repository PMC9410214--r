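## Preprocessing chain applied to raw smear images before hexagonal-trellis
## filtering: crop/resize -> complement -> dehaze -> inverse complement ->
## grayscale.

pad_indices <- function(n, r, mode) {
  switch(mode,
    replicate = c(rep(1L, r), seq_len(n), rep(n, r)),
    reflect   = c(rev(seq_len(min(r, n))), seq_len(n),
                  rev(seq_len(n))[seq_len(min(r, n))]),
    zero      = NULL,
    stop("unknown border mode '", mode, "'")
  )
}

pad_matrix <- function(m, r, mode = "replicate", fill = 0) {
  if (r == 0L) return(m)
  if (mode == "zero") {
    out <- matrix(fill, nrow(m) + 2 * r, ncol(m) + 2 * r)
    out[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m))] <- m
    return(out)
  }
  m[pad_indices(nrow(m), r, mode), pad_indices(ncol(m), r, mode)]
}

## minimum filter with a (2r+1)^2 window, replicate border (equivalent to the
## minimum over the in-bounds part of each window)
min_filter <- function(m, r) {
  p <- pad_matrix(m, r, "replicate")
  out <- NULL
  for (dr in 0:(2 * r)) {
    for (dc in 0:(2 * r)) {
      s <- p[(1 + dr):(nrow(m) + dr), (1 + dc):(ncol(m) + dc), drop = FALSE]
      out <- if (is.null(out)) s else pmin(out, s)
    }
  }
  out
}

#' Crop and resize an image
#'
#' Extracts a rectangular region and resamples it to the requested output
#' size. Used to trim the dark frame around microscope fields and normalize
#' all images to a common raster (the smear datasets this mirrors are
#' 320 x 240 RGB).
#'
#' @param img RGB array or grayscale matrix.
#' @param box integer vector `c(top, left, height, width)` (1-based) or
#'   `NULL` for the full frame.
#' @param out_h,out_w output dimensions (rows, columns), both >= 3.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return resampled image of dimensions `out_h` x `out_w`.
#' @export
crop_resize <- function(img, box = NULL, out_h = NULL, out_w = NULL,
                        method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  gray <- is.matrix(img)
  if (gray) assert_gray(img, 3L) else assert_rgb(img, 3L)
  d <- dim(img)
  if (is.null(box)) box <- c(1L, 1L, d[1], d[2])
  box <- as.integer(box)
  if (length(box) != 4L || any(is.na(box)))
    stop("box must be c(top, left, height, width)", call. = FALSE)
  if (box[1] < 1L || box[2] < 1L || box[3] < 1L || box[4] < 1L ||
      box[1] + box[3] - 1L > d[1] || box[2] + box[4] - 1L > d[2])
    stop("crop box lies outside the image", call. = FALSE)
  if (is.null(out_h)) out_h <- box[3]
  if (is.null(out_w)) out_w <- box[4]
  if (out_h < 3L || out_w < 3L) stop("output must be at least 3 x 3",
                                     call. = FALSE)
  rows <- box[1]:(box[1] + box[3] - 1L)
  cols <- box[2]:(box[2] + box[4] - 1L)
  sub <- if (gray) img[rows, cols, drop = FALSE] else img[rows, cols, , drop = FALSE]
  resize_plane <- function(m) {
    h <- nrow(m); w <- ncol(m)
    # pixel-centre mapping; reduces to identity when sizes match
    sy <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
    sx <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
    if (method == "nearest") {
      iy <- pmin(pmax(round_half_up(sy), 1), h)
      ix <- pmin(pmax(round_half_up(sx), 1), w)
      return(m[iy, ix, drop = FALSE])
    }
    y0 <- pmin(pmax(floor(sy), 1), h); y1 <- pmin(y0 + 1, h)
    x0 <- pmin(pmax(floor(sx), 1), w); x1 <- pmin(x0 + 1, w)
    fy <- pmin(pmax(sy - y0, 0), 1);   fx <- pmin(pmax(sx - x0, 0), 1)
    a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
    c_ <- m[y1, x0, drop = FALSE]; d_ <- m[y1, x1, drop = FALSE]
    wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
    a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx +
      c_ * wy * (1 - wx) + d_ * wy * wx
  }
  if (gray) return(clip8(resize_plane(sub)))
  out <- array(NA_real_, c(out_h, out_w, 3L))
  for (c in 1:3) out[, , c] <- resize_plane(sub[, , c])
  clip8(out)
}

#' Image complement
#'
#' Per-channel intensity inversion `v -> 255 - v`. On stained smears this
#' turns the bright background dark so that the dark-channel dehazing prior
#' becomes applicable; it is its own inverse.
#'
#' @param img RGB array or grayscale matrix.
#' @return complemented image, same dimensions.
#' @export
img_complement <- function(img) {
  if (is.matrix(img)) assert_gray(img) else assert_rgb(img, 1L)
  255 - img
}

#' Dark channel of an RGB image
#'
#' At each position, the minimum over a `patch_size` x `patch_size`
#' neighborhood of the per-pixel channel minimum. Haze-free natural patches
#' tend to have a near-zero dark channel; haze lifts it toward the
#' atmospheric light.
#'
#' @param img RGB array.
#' @param patch_size odd window edge length, >= 3.
#' @return matrix of dark-channel values.
#' @export
dark_channel <- function(img, patch_size = 15L) {
  assert_rgb(img)
  patch_size <- as.integer(patch_size)
  if (is.na(patch_size) || patch_size < 3L || patch_size %% 2L == 0L)
    stop("patch_size must be odd and >= 3", call. = FALSE)
  min_filter(pmin(img[, , 1], img[, , 2], img[, , 3]), (patch_size - 1L) %/% 2L)
}

#' Transmission map estimate
#'
#' `T = 1 - dark_channel(I / A)` with the image normalized channelwise by the
#' atmospheric light `A`, clipped to \[0, 1\].
#'
#' @param img RGB array.
#' @param atmos per-channel atmospheric light, all components > 0 (a scalar
#'   is recycled).
#' @inheritParams dark_channel
#' @return matrix of transmission values in \[0, 1\].
#' @export
transmission_map <- function(img, atmos, patch_size = 15L) {
  assert_rgb(img)
  atmos <- rep_len(as.numeric(atmos), 3L)
  if (anyNA(atmos) || any(atmos <= 0))
    stop("atmospheric light components must be > 0", call. = FALSE)
  patch_size <- as.integer(patch_size)
  if (is.na(patch_size) || patch_size < 3L || patch_size %% 2L == 0L)
    stop("patch_size must be odd and >= 3", call. = FALSE)
  norm <- img
  for (c in 1:3) norm[, , c] <- img[, , c] / atmos[c]
  t_map <- 1 - min_filter(pmin(norm[, , 1], norm[, , 2], norm[, , 3]),
                          (patch_size - 1L) %/% 2L)
  pmin(pmax(t_map, 0), 1)
}

#' Estimate atmospheric light from the brightest dark-channel pixels
#'
#' Per-channel mean of the input pixels whose dark-channel value falls in the
#' top `quantile` fraction (the haze-opaque region, when one exists).
#'
#' @inheritParams dark_channel
#' @param quantile fraction of brightest dark-channel pixels to average.
#' @return numeric length-3 atmospheric light, each component >= 1.
#' @export
estimate_atmos <- function(img, patch_size = 15L, quantile = 0.001) {
  assert_rgb(img)
  dc <- dark_channel(img, patch_size)
  thr <- stats::quantile(dc, 1 - quantile, names = FALSE)
  sel <- dc >= thr
  a <- vapply(1:3, function(c) mean(img[, , c][sel]), numeric(1))
  pmax(a, 1)
}

#' Dehazing parameters
#'
#' Bundles the knobs of the scattering-model restoration: the dark-channel
#' patch size, an optional gamma correction applied after restoration, the
#' transmission floor that limits amplification in dense haze, the quantile
#' used to estimate atmospheric light, and an optional explicit
#' atmospheric-light estimate that bypasses estimation (useful when the haze
#' source is known, e.g. for synthetic scenes).
#'
#' @param patch_size odd integer >= 3; dark-channel window (default 15).
#' @param gamma post-restoration gamma exponent, > 0; 1 disables (default).
#' @param t_floor lower transmission bound in (0, 1) (default 0.1).
#' @param atmos_quantile fraction in (0, 1) of brightest dark-channel pixels
#'   averaged for the atmospheric-light estimate (default 0.001).
#' @param atmos optional per-channel atmospheric light; `NULL` (default)
#'   estimates it from the image.
#' @return an object of class `dehaze_params`.
#' @export
dehaze_params <- function(patch_size = 15L, gamma = 1, t_floor = 0.1,
                          atmos_quantile = 0.001, atmos = NULL) {
  patch_size <- as.integer(patch_size)
  if (is.na(patch_size) || patch_size < 3L || patch_size %% 2L == 0L)
    stop("patch_size must be odd and >= 3", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0",
                                             call. = FALSE)
  if (!is.numeric(t_floor) || t_floor <= 0 || t_floor >= 1)
    stop("t_floor must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(atmos_quantile) || atmos_quantile <= 0 ||
      atmos_quantile >= 1)
    stop("atmos_quantile must lie in (0, 1)", call. = FALSE)
  if (!is.null(atmos)) {
    atmos <- rep_len(as.numeric(atmos), 3L)
    if (anyNA(atmos) || any(atmos <= 0))
      stop("atmos components must be > 0", call. = FALSE)
  }
  structure(list(patch_size = patch_size, gamma = gamma, t_floor = t_floor,
                 atmos_quantile = atmos_quantile, atmos = atmos),
            class = "dehaze_params")
}

#' Dehaze an RGB image
#'
#' Inverts the scattering model `I = J t + A (1 - t)`: atmospheric light `A`
#' is taken from `params$atmos` or estimated from the brightest dark-channel
#' quantile, the transmission map `t` from the dark channel of `I / A`, and
#' the scene is restored as `J = (I - A) / max(t, t_floor) + A`, followed by
#' optional gamma correction and 8-bit clipping. A constant (degenerate)
#' image is returned unchanged with a warning.
#'
#' The restoration is only quantitatively faithful where the dark-channel
#' prior holds for the underlying scene (some near-zero channel minimum in
#' every patch); elsewhere it acts as a contrast amplifier, which is how it
#' is used in the smear-enhancement chain.
#'
#' @param img RGB array.
#' @param params a [dehaze_params()] object.
#' @return restored RGB array, same dimensions.
#' @export
dehaze <- function(img, params = dehaze_params()) {
  assert_rgb(img)
  if (!inherits(params, "dehaze_params"))
    stop("params must be a dehaze_params object", call. = FALSE)
  if (max(img) == min(img)) {
    warning("degenerate constant image: returning it unchanged")
    return(img)
  }
  a <- if (is.null(params$atmos))
    estimate_atmos(img, params$patch_size, params$atmos_quantile)
  else params$atmos
  t_map <- transmission_map(img, a, params$patch_size)
  t_eff <- pmax(t_map, params$t_floor)
  out <- img
  for (c in 1:3) out[, , c] <- (img[, , c] - a[c]) / t_eff + a[c]
  out <- pmin(pmax(out, 0), 255)
  if (params$gamma != 1) out <- 255 * (out / 255)^params$gamma
  clip8(out)
}

#' Convert RGB to grayscale
#'
#' Luminance-weighted combination with BT.601 weights
#' (0.299, 0.587, 0.114), rounded half-up to 8-bit.
#'
#' @param img RGB array.
#' @return grayscale matrix.
#' @export
to_grayscale <- function(img) {
  assert_rgb(img, 1L)
  clip8(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
}

#' Full preprocessing chain for a smear image
#'
#' Crop/resize, then (optionally) complement, dehaze, inverse-complement,
#' and convert to grayscale — the normalization applied before the
#' hexagonal-trellis filter. Dehazing is run on the complemented image when
#' `complement_chain` is `TRUE` (the default), because the dehazing prior
#' expects a dark background.
#'
#' @param img RGB array.
#' @param box,out_h,out_w passed to [crop_resize()]; `NULL` keeps the frame.
#' @param complement_chain run complement -> dehaze -> inverse complement.
#' @param run_dehaze apply the dehazing step at all.
#' @param params a [dehaze_params()] object.
#' @return grayscale matrix ready for filtering.
#' @export
preprocess_smear <- function(img, box = NULL, out_h = NULL, out_w = NULL,
                             complement_chain = TRUE, run_dehaze = TRUE,
                             params = dehaze_params()) {
  assert_rgb(img)
  if (!is.null(box) || !is.null(out_h) || !is.null(out_w))
    img <- crop_resize(img, box, out_h, out_w)
  if (run_dehaze) {
    if (complement_chain) {
      img <- img_complement(dehaze(img_complement(img), params))
    } else {
      img <- dehaze(img, params)
    }
  }
  to_grayscale(img)
}
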