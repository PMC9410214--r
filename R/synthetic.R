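## Seeded generator of WBC-smear-like images: bright pinkish background,
## an elliptical cytoplasm, a darker (possibly multi-lobed) nucleus,
## platelet speckles, Gaussian blur, additive noise — plus a constant-
## transmission haze overlay with a known forward model, so that every
## pipeline stage has a testable ground truth without any dataset download.

#' Parameters of the synthetic smear generator
#'
#' Defaults emulate a 320 x 240 RGB smear crop centred on one leukocyte.
#' The palette (background (230,200,210), cytoplasm (200,160,200), nucleus
#' (90,50,130)) mimics a Giemsa-stained smear; `nucleus_lobes = 1` gives
#' the round nucleus of a lymphocyte/monocyte, 2–5 the lobed nucleus of a
#' neutrophil/eosinophil.
#'
#' @param height,width frame size in pixels (default 240 x 320).
#' @param cell_radius_range interval (pixels) the cytoplasm semi-major axis
#'   is drawn from.
#' @param nucleus_lobes number of nucleus lobes, >= 1.
#' @param haze_t default haze transmission in (0, 1] used by [add_haze()].
#' @param atmos default per-channel haze light level.
#' @param blur_sigma Gaussian blur sigma in pixels (0 disables).
#' @param noise_sigma additive Gaussian noise sigma in intensity levels.
#' @param n_platelets number of platelet speckles scattered in the frame.
#' @param seed RNG seed making the image reproducible.
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(height = 240L, width = 320L,
                         cell_radius_range = c(45, 60),
                         nucleus_lobes = 3L,
                         haze_t = 0.6, atmos = c(220, 220, 220),
                         blur_sigma = 1, noise_sigma = 4,
                         n_platelets = 25L, seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 16L || width < 16L) stop("frame must be at least 16 x 16",
                                        call. = FALSE)
  cell_radius_range <- sort(as.numeric(cell_radius_range))
  if (length(cell_radius_range) != 2L || cell_radius_range[1] <= 0)
    stop("cell_radius_range must be a positive interval", call. = FALSE)
  if (2 * cell_radius_range[2] >= min(height, width))
    stop("cell does not fit inside the frame", call. = FALSE)
  if (nucleus_lobes < 1L) stop("nucleus_lobes must be >= 1", call. = FALSE)
  if (haze_t <= 0 || haze_t > 1) stop("haze_t must lie in (0, 1]",
                                      call. = FALSE)
  if (blur_sigma < 0 || noise_sigma < 0)
    stop("blur_sigma and noise_sigma must be >= 0", call. = FALSE)
  structure(list(height = height, width = width,
                 cell_radius_range = cell_radius_range,
                 nucleus_lobes = as.integer(nucleus_lobes),
                 haze_t = haze_t, atmos = rep_len(as.numeric(atmos), 3L),
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 n_platelets = as.integer(n_platelets),
                 seed = as.integer(seed)),
            class = "synth_params")
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_taps(sigma)
  if (is.matrix(img)) return(conv_sep(img, k))
  for (c in 1:3) img[, , c] <- conv_sep(img[, , c], k)
  img
}

#' Generate a synthetic WBC smear image
#'
#' Draws one leukocyte (elliptical cytoplasm with a darker lobed nucleus)
#' on a bright pinkish background with platelet speckles, then applies
#' Gaussian blur and additive noise. Deterministic for a fixed seed.
#'
#' @param params a [synth_params()] object.
#' @return list with components `clean` (H x W x 3 array), `nucleus_mask`
#'   (logical matrix), and `params`.
#' @export
generate_wbc_image <- function(params = synth_params()) {
  if (!inherits(params, "synth_params"))
    stop("params must be a synth_params object", call. = FALSE)
  withr::with_seed(params$seed, {
    h <- params$height; w <- params$width
    bg  <- c(230, 200, 210)
    cyt <- c(200, 160, 200)
    nuc <- c(90, 50, 130)
    plt <- c(120, 70, 140)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)

    cy <- h / 2 + stats::runif(1, -h / 12, h / 12)
    cx <- w / 2 + stats::runif(1, -w / 12, w / 12)
    a <- stats::runif(1, params$cell_radius_range[1],
                      params$cell_radius_range[2])
    b <- a * stats::runif(1, 0.75, 1)
    th <- stats::runif(1, 0, pi)
    u <- (yy - cy) * cos(th) - (xx - cx) * sin(th)
    v <- (yy - cy) * sin(th) + (xx - cx) * cos(th)
    cell <- (u / b)^2 + (v / a)^2 <= 1

    # nucleus: overlapping discs around the cell centre
    lobes <- params$nucleus_lobes
    r_lobe <- 0.45 * min(a, b) / max(1, lobes)^0.35
    spread <- if (lobes == 1) 0 else 0.35 * min(a, b)
    ang0 <- stats::runif(1, 0, 2 * pi)
    mask <- matrix(FALSE, h, w)
    for (l in seq_len(lobes)) {
      ang <- ang0 + 2 * pi * (l - 1) / lobes
      ly <- cy + spread * sin(ang); lx <- cx + spread * cos(ang)
      mask <- mask | ((yy - ly)^2 + (xx - lx)^2 <= r_lobe^2)
    }
    mask <- mask & cell

    img <- array(0, c(h, w, 3L))
    for (c in 1:3) {
      plane <- matrix(bg[c], h, w)
      plane[cell] <- cyt[c]
      plane[mask] <- nuc[c]
      img[, , c] <- plane
    }

    # platelet speckles on the background
    if (params$n_platelets > 0) {
      py <- stats::runif(params$n_platelets, 4, h - 3)
      px <- stats::runif(params$n_platelets, 4, w - 3)
      pr <- stats::runif(params$n_platelets, 1.5, 3.5)
      for (i in seq_len(params$n_platelets)) {
        disc <- (yy - py[i])^2 + (xx - px[i])^2 <= pr[i]^2 & !cell
        for (c in 1:3) {
          plane <- img[, , c]
          plane[disc] <- plt[c]
          img[, , c] <- plane
        }
      }
    }

    img <- gaussian_blur(img, params$blur_sigma)
    if (params$noise_sigma > 0)
      img <- img + array(stats::rnorm(length(img), 0, params$noise_sigma),
                         dim(img))
    list(clean = clip8(img), nucleus_mask = mask, params = params)
  })
}

#' Overlay synthetic haze
#'
#' Applies the scattering forward model `I = clean * t + atmos * (1 - t)`
#' with spatially constant transmission `t`, rounded and clipped to 8-bit.
#' This is the model the dehazing stage inverts.
#'
#' @param clean RGB array.
#' @param t transmission in (0, 1]; 1 leaves the image unchanged.
#' @param atmos per-channel haze light level (scalar recycled).
#' @return hazed RGB array.
#' @export
add_haze <- function(clean, t, atmos = c(220, 220, 220)) {
  assert_rgb(clean)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0 || t > 1)
    stop("t must lie in (0, 1]", call. = FALSE)
  atmos <- rep_len(as.numeric(atmos), 3L)
  out <- clean
  for (c in 1:3) out[, , c] <- clean[, , c] * t + atmos[c] * (1 - t)
  clip8(out)
}
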