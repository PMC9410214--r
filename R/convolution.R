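## Single-stride 3x3 convolution with explicit border and rounding
## contracts.  All arithmetic is exact integer arithmetic: for a weight sum
## s and normalizer cff,
##   floor    -> s %/% cff
##   half_up  -> (2 s + cff) %/% (2 cff)
##   ceil     -> (s + cff - 1) %/% cff
## so no floating-point rounding ambiguity can enter.

round_div <- function(s, cff, rounding) {
  switch(rounding,
    floor   = s %/% cff,
    half_up = (2 * s + cff) %/% (2 * cff),
    ceil    = (s + cff - 1) %/% cff,
    stop("unknown rounding mode '", rounding, "'")
  )
}

#' Filter configuration
#'
#' Border and rounding contracts for [filter_image()]. The default rounding
#' is `half_up`; `ceil` is the mode that reproduces the published worked
#' example of the hexagonal filter (whose exact quotient 59/14 is printed as
#' 5). Border `replicate` keeps output dimensions equal to input.
#'
#' @param rounding one of `"half_up"`, `"floor"`, `"ceil"`.
#' @param border one of `"replicate"`, `"reflect"`, `"zero"`.
#' @param clip force the output into \[0, 255\] (default `TRUE`).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(rounding = c("half_up", "floor", "ceil"),
                          border = c("replicate", "reflect", "zero"),
                          clip = TRUE) {
  structure(list(rounding = match.arg(rounding), border = match.arg(border),
                 clip = isTRUE(clip)),
            class = "filter_config")
}

#' Response of the kernel on a single 3x3 patch
#'
#' Computes `round(sum(weights * patch) / cff)` under the chosen rounding
#' mode, clipped to \[0, 255\]. This is the per-stride step of the
#' convolution; the published worked example is
#' `patch_response(rbind(c(3,0,1), c(6,6,2), c(2,4,1)), derive_kernel(14),
#' rounding = "ceil") == 5`.
#'
#' @param patch 3x3 numeric matrix of intensities.
#' @param kernel a [derive_kernel()] object (or any 3x3 integer matrix).
#' @param rounding rounding mode, see [filter_config()].
#' @return a single intensity in \[0, 255\].
#' @export
patch_response <- function(patch, kernel = derive_kernel(),
                           rounding = c("half_up", "floor", "ceil")) {
  rounding <- match.arg(rounding)
  if (!is.matrix(patch) || !identical(dim(patch), c(3L, 3L)))
    stop("patch must be a 3 x 3 matrix", call. = FALSE)
  w <- if (inherits(kernel, "vht_kernel")) kernel$weights else kernel
  cff <- if (inherits(kernel, "vht_kernel")) kernel$cff else sum(w)
  s <- sum(round_half_up(patch) * w)
  min(max(round_div(s, cff, rounding), 0), 255)
}

#' Apply a 3x3 kernel over a grayscale image with single stride
#'
#' Slides the kernel with stride 1 in both axes; every pixel of the
#' same-size output is the [patch_response()] of its 3x3 neighborhood, with
#' the border completed according to `config$border`. Because the
#' hexagonal-trellis kernel is symmetric under 180-degree rotation, true
#' convolution (flipped kernel) and correlation coincide.
#'
#' @param img grayscale matrix, at least 3 x 3.
#' @param kernel a [derive_kernel()] object or 3x3 integer matrix.
#' @param config a [filter_config()] object.
#' @return filtered grayscale matrix, same dimensions as `img`.
#' @export
filter_image <- function(img, kernel = derive_kernel(),
                         config = filter_config()) {
  assert_gray(img, 3L)
  if (!inherits(config, "filter_config"))
    stop("config must be a filter_config object", call. = FALSE)
  w <- if (inherits(kernel, "vht_kernel")) kernel$weights else kernel
  if (!is.matrix(w) || !identical(dim(w), c(3L, 3L)))
    stop("kernel must be 3 x 3", call. = FALSE)
  cff <- if (inherits(kernel, "vht_kernel")) kernel$cff else sum(w)
  h <- nrow(img); wd <- ncol(img)
  p <- pad_matrix(round_half_up(img), 1L, config$border)
  s <- matrix(0, h, wd)
  for (dr in 0:2) {
    for (dc in 0:2) {
      if (w[dr + 1, dc + 1] == 0) next
      s <- s + w[dr + 1, dc + 1] *
        p[(1 + dr):(h + dr), (1 + dc):(wd + dc), drop = FALSE]
    }
  }
  out <- round_div(s, cff, config$rounding)
  if (config$clip) out <- pmin(pmax(out, 0), 255)
  out
}
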