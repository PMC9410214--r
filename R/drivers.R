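## Experiment drivers mirroring the evaluation protocol: the constant-
## filter-factor sweep, the four-method comparison, and the alpha sweep.
## The filtered image is always scored against the pre-filter (dehazed
## grayscale) image, the only reference that exists in this protocol.

#' Sweep the constant filter factor
#'
#' Filters `original` with the hexagonal-trellis kernel for every CFF in
#' `cffs` and reports PSNR/MSE of the filtered image against the input.
#' Since the weights sum to 14, CFF 14 is the unit-gain point where
#' distortion is smallest; PSNR and MSE rows are anti-monotone to each
#' other by construction.
#'
#' @param original grayscale matrix (typically the dehazed grayscale
#'   image entering the filter).
#' @param cffs integer vector of normalizers, default `7:19`.
#' @param config a [filter_config()] object.
#' @return `data.frame` with columns `cff`, `psnr`, `mse`, one row per CFF.
#' @export
sweep_cff <- function(original, cffs = 7:19, config = filter_config()) {
  assert_gray(original, 3L)
  cffs <- as.integer(cffs)
  if (length(cffs) == 0L || anyNA(cffs) || any(cffs < 1L))
    stop("cffs must be a nonempty vector of positive integers", call. = FALSE)
  rows <- lapply(cffs, function(cff) {
    out <- filter_image(original, derive_kernel(cff), config)
    em <- error_metrics(original, out)
    data.frame(cff = cff, psnr = em$psnr, mse = em$mse)
  })
  do.call(rbind, rows)
}

#' Compare enhancement methods
#'
#' Applies each requested method to `original` and scores the result
#' against it with the six-metric panel (PSNR, MSE, SSIM, entropy, NAE,
#' NCC). Methods: `vhf` (the hexagonal-trellis filter at `cff`), `he`
#' (histogram equalization), `mean` (3x3 box mean), `wiener` (3x3 adaptive
#' Wiener).
#'
#' @param original grayscale matrix.
#' @param methods subset of `c("vhf", "he", "mean", "wiener")`.
#' @param cff normalizer used for the `vhf` method.
#' @param config a [filter_config()] object (used by `vhf` and `mean`).
#' @return `data.frame` with one row per method and columns `method`,
#'   `psnr`, `mse`, `ssim`, `entropy`, `nae`, `ncc`.
#' @export
compare_methods <- function(original,
                            methods = c("vhf", "he", "mean", "wiener"),
                            cff = 14L, config = filter_config()) {
  assert_gray(original, 11L)
  methods <- unique(methods)
  bad <- setdiff(methods, c("vhf", "he", "mean", "wiener"))
  if (length(methods) == 0L || length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  rows <- lapply(methods, function(m) {
    out <- switch(m,
      vhf    = filter_image(original, derive_kernel(cff), config),
      he     = apply_reference_filter(original, "histogram_equalization"),
      mean   = apply_reference_filter(original, "mean3x3", config),
      wiener = apply_reference_filter(original, "wiener3x3"))
    em <- error_metrics(original, out)
    data.frame(method = m, psnr = em$psnr, mse = em$mse,
               ssim = ssim(original, out), entropy = img_entropy(out),
               nae = em$nae, ncc = em$ncc)
  })
  do.call(rbind, rows)
}

#' Mean row for a batch of comparison tables
#'
#' Column means of the per-image method tables, one row per method —
#' the "mean values of different metrics" convention for batch reports.
#'
#' @param tables list of `data.frame`s from [compare_methods()].
#' @return `data.frame` of per-method column means.
#' @export
mean_comparison <- function(tables) {
  if (!length(tables)) stop("no tables supplied", call. = FALSE)
  all_rows <- do.call(rbind, tables)
  num_cols <- setdiff(names(all_rows), "method")
  agg <- stats::aggregate(all_rows[num_cols], list(method = all_rows$method),
                          mean)
  agg[match(unique(all_rows$method), agg$method), , drop = FALSE]
}

#' Alpha-rooting sweep
#'
#' EME of alpha-rooted versions of a reference image and a degraded
#' companion, over a grid of alpha values. The `alpha = 1` row reproduces
#' the plain (un-rooted) EME of both images.
#'
#' @param original,noisy grayscale matrices.
#' @param alphas positive alpha values, default `seq(0.2, 1.1, by = 0.1)`.
#' @param block_h,block_w EME block size in pixels.
#' @return `data.frame` with columns `alpha`, `eme_original`, `eme_noisy`.
#' @export
alpha_sweep <- function(original, noisy, alphas = seq(0.2, 1.1, by = 0.1),
                        block_h = 8L, block_w = 8L) {
  assert_gray(original); assert_gray(noisy)
  if (length(alphas) == 0L || any(!is.finite(alphas)) || any(alphas <= 0))
    stop("alphas must be a nonempty vector of positive numbers",
         call. = FALSE)
  rows <- lapply(alphas, function(a) {
    data.frame(alpha = a,
               eme_original = eme(alpha_rooting(original, a),
                                  block_h, block_w),
               eme_noisy = eme(alpha_rooting(noisy, a), block_h, block_w))
  })
  do.call(rbind, rows)
}
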