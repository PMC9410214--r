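#' hexatrellis: virtual hexagonal trellis filtering for blood-smear images
#'
#' Images are represented with plain base-R containers, the convention of
#' array-based image packages: a grayscale image is an H x W numeric matrix
#' and an RGB image an H x W x 3 numeric array, both holding 8-bit
#' intensities in \[0, 255\]. Row 1 is the top image row.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft quantile
#' @importFrom utils write.csv
NULL

#' Validate a grayscale image
#'
#' Checks that `img` is a numeric matrix with all intensities in \[0, 255\].
#'
#' @param img object to check.
#' @param min_dim minimum number of rows and columns required.
#' @return `img`, invisibly.
#' @export
assert_gray <- function(img, min_dim = 1L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("grayscale image must be a numeric matrix", call. = FALSE)
  if (nrow(img) < min_dim || ncol(img) < min_dim)
    stop(sprintf("image must be at least %d x %d", min_dim, min_dim),
         call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("intensities must lie in [0, 255] with no NA", call. = FALSE)
  invisible(img)
}

#' Validate an RGB image
#'
#' Checks that `img` is an H x W x 3 numeric array with intensities in
#' \[0, 255\] and spatial extent at least `min_dim`.
#'
#' @inheritParams assert_gray
#' @return `img`, invisibly.
#' @export
assert_rgb <- function(img, min_dim = 3L) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L ||
      !is.numeric(img))
    stop("RGB image must be an H x W x 3 numeric array", call. = FALSE)
  if (dim(img)[1] < min_dim || dim(img)[2] < min_dim)
    stop(sprintf("image must be at least %d x %d", min_dim, min_dim),
         call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("intensities must lie in [0, 255] with no NA", call. = FALSE)
  invisible(img)
}

## round half away from zero (pixels are nonnegative, so: half up)
round_half_up <- function(x) floor(x + 0.5)

#' Clip and quantize to 8-bit intensities
#'
#' @param x numeric matrix or array.
#' @param quantize round to whole intensity levels (half-up)?
#' @return `x` limited to \[0, 255\].
#' @export
clip8 <- function(x, quantize = TRUE) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  if (quantize) x <- round_half_up(x)
  x
}

## ---- Netpbm (PGM/PPM) I/O -------------------------------------------------
## Base R has no raster-format reader and no image-I/O package is assumed, so
## the package speaks the Netpbm family: P2/P5 (PGM, gray), P3/P6 (PPM, RGB).

pnm_header <- function(con) {
  # token reader that skips whitespace and '#' comments
  tokens <- character(0)
  repeat {
    if (length(tokens) >= 4L) break
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || !nzchar(ch)) stop("truncated PNM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) next
    tok <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || grepl("[[:space:]]", ch)) break
      if (ch == "#") { # comment glued to token end
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
        break
      }
      tok <- paste0(tok, ch)
    }
    tokens <- c(tokens, tok)
    if (length(tokens) == 1L && !tokens %in% c("P2", "P3", "P5", "P6"))
      stop("unsupported PNM magic '", tokens, "'")
  }
  list(magic = tokens[1],
       width = as.integer(tokens[2]),
       height = as.integer(tokens[3]),
       maxval = as.integer(tokens[4]))
}

#' Read a PGM or PPM image
#'
#' Supports ASCII (P2/P3) and binary (P5/P6) Netpbm rasters with
#' `maxval <= 65535`. Images with `maxval != 255` are linearly rescaled to
#' \[0, 255\] with a warning, so downstream code always sees 8-bit data.
#'
#' @param path file path.
#' @return a grayscale matrix (PGM) or an H x W x 3 array (PPM).
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- pnm_header(con)
  if (is.na(h$width) || is.na(h$height) || is.na(h$maxval) ||
      h$width < 1L || h$height < 1L || h$maxval < 1L)
    stop("malformed PNM header in ", path)
  nch <- if (h$magic %in% c("P3", "P6")) 3L else 1L
  n <- h$width * h$height * nch
  if (h$magic %in% c("P2", "P3")) {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE,
                 comment.char = "#")
  } else {
    bytes_per <- if (h$maxval > 255L) 2L else 1L
    vals <- readBin(con, "integer", n = n, size = bytes_per,
                    signed = FALSE, endian = "big")
  }
  if (length(vals) != n) stop("truncated pixel data in ", path)
  if (h$maxval != 255L) {
    warning("rescaling maxval ", h$maxval, " image to [0, 255]")
    vals <- round_half_up(vals * (255 / h$maxval))
  }
  # PNM is row-major, top row first; channel fastest for PPM
  if (nch == 1L) {
    matrix(as.numeric(vals), nrow = h$height, ncol = h$width, byrow = TRUE)
  } else {
    a <- array(NA_real_, c(h$height, h$width, 3L))
    for (c in 1:3)
      a[, , c] <- matrix(as.numeric(vals[seq(c, n, by = 3L)]),
                         nrow = h$height, ncol = h$width, byrow = TRUE)
    a
  }
}

#' Write a PGM or PPM image
#'
#' Grayscale matrices are written as PGM, RGB arrays as PPM. Intensities are
#' clipped/rounded to 8-bit first.
#'
#' @param img grayscale matrix or H x W x 3 array.
#' @param path output file path; conventional extensions are `.pgm`/`.ppm`.
#' @param ascii write the ASCII (P2/P3) variant instead of binary (P5/P6).
#' @return `path`, invisibly.
#' @export
write_pnm <- function(img, path, ascii = FALSE) {
  gray <- is.matrix(img)
  if (gray) assert_gray(img, 1L) else assert_rgb(img, 1L)
  img <- clip8(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (gray) {
    vals <- as.integer(t(img))
  } else {
    vals <- as.integer(aperm(img, c(3, 2, 1))) # channel fastest, row-major
  }
  magic <- if (ascii) (if (gray) "P2" else "P3") else (if (gray) "P5" else "P6")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", magic, w, h), con, eos = NULL)
  if (ascii) {
    writeChar(paste(vals, collapse = "\n"), con, eos = NULL)
    writeChar("\n", con, eos = NULL)
  } else {
    writeBin(vals, con, size = 1L)
  }
  invisible(path)
}
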