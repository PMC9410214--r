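## Derivation of the virtual-hexagonal-trellis (VHT) kernel.
##
## A 3x3 square neighborhood has four edge pixels R1..R4 at unit distance
## from the centre C1 and four corner pixels N1..N4 slightly further out.
## Virtual pixels V1..V4 are placed at the midpoints between each corner and
## the centre, valued at their arithmetic mean; the hexagonal neighborhood is
## the seven-sample set {V1, V2, R1, C1, R4, V3, V4} (the two vertical edge
## pixels R2, R3 are dropped). Averaging those seven samples and clearing
## the denominator yields an integer 3x3 mask whose normalizer is exposed as
## the "constant filter factor" (CFF).

## symbols of the 3x3 grid in layout order:
## row 1 = (N1, R2, N2), row 2 = (R1, C1, R4), row 3 = (N3, R3, N4)
vht_symbols <- matrix(c("N1", "R2", "N2",
                        "R1", "C1", "R4",
                        "N3", "R3", "N4"), 3, 3, byrow = TRUE)

#' Virtual pixel intensity
#'
#' The virtual sample midway between a corner neighbor and the central
#' pixel, valued at their exact (unrounded) arithmetic mean.
#'
#' @param corner,centre intensities in \[0, 255\].
#' @return `(corner + centre) / 2`, possibly fractional.
#' @export
virtual_pixel_intensity <- function(corner, centre) {
  if (!is.numeric(corner) || !is.numeric(centre) ||
      anyNA(c(corner, centre)) ||
      any(corner < 0 | corner > 255) || any(centre < 0 | centre > 255))
    stop("intensities must lie in [0, 255]", call. = FALSE)
  (corner + centre) / 2
}

## a linear form over the nine grid symbols, stored as rational coefficients
## (integer numerators over one common denominator)
linform <- function(num = integer(9), den = 1L) {
  names(num) <- as.vector(t(vht_symbols))
  list(num = num, den = den)
}

lf_add_symbol <- function(lf, sym, num, den) {
  # add (num/den) * sym, keeping one common denominator
  l <- lf$den * den %/% gcd2(lf$den, den) # lcm
  lf$num <- lf$num * (l %/% lf$den)
  lf$num[sym] <- lf$num[sym] + num * (l %/% den)
  lf$den <- l
  lf
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

## Expand the seven-term hexagonal average symbolically.  Each virtual pixel
## contributes (N_k + C1)/2; the result is returned with all coefficients
## integer over a single denominator.
derive_vht_form <- function() {
  terms <- list(
    list(sym = "V1"), list(sym = "V2"), list(sym = "R1"), list(sym = "C1"),
    list(sym = "R4"), list(sym = "V3"), list(sym = "V4")
  )
  n_terms <- length(terms)
  lf <- linform()
  for (tm in terms) {
    if (grepl("^V", tm$sym)) {
      corner <- sub("V", "N", tm$sym)
      lf <- lf_add_symbol(lf, corner, 1L, 2L)
      lf <- lf_add_symbol(lf, "C1", 1L, 2L)
    } else {
      lf <- lf_add_symbol(lf, tm$sym, 1L, 1L)
    }
  }
  # the average over the seven samples
  lf$den <- lf$den * n_terms
  # clear the denominator so every coefficient is integer; what remains in
  # `den` is the normalizer at which the mask has unit DC gain
  g <- Reduce(gcd2, c(abs(lf$num[lf$num != 0L]), lf$den))
  lf$num <- lf$num %/% g
  lf$den <- lf$den %/% g
  lf
}

#' Derive the virtual-hexagonal-trellis kernel
#'
#' Performs the virtual-pixel substitution `V_k = (N_k + C1) / 2` in the
#' seven-sample hexagonal average and clears the common denominator,
#' producing the integer mask
#' \preformatted{ 1 0 1
#'  2 6 2
#'  1 0 1 }
#' whose weights sum to 14. The normalizing divisor (constant filter
#' factor, CFF) is a free parameter; at `cff = 14` the filter has unit DC
#' gain, and the sweep explored in practice runs over 7..19.
#'
#' @param cff positive integer normalizer.
#' @return an object of class `vht_kernel` with fields `weights` (3x3
#'   integer matrix), `cff`, and `gain` (= sum(weights)/cff).
#' @export
derive_kernel <- function(cff = 14L) {
  cff <- as.integer(cff)
  if (is.na(cff) || cff < 1L) stop("cff must be a positive integer",
                                   call. = FALSE)
  lf <- derive_vht_form()
  weights <- matrix(unname(lf$num[as.vector(t(vht_symbols))]), 3, 3,
                    byrow = TRUE)
  structure(list(weights = weights, cff = cff,
                 gain = sum(weights) / cff,
                 derived_normalizer = lf$den),
            class = "vht_kernel")
}

#' @export
print.vht_kernel <- function(x, ...) {
  cat("virtual hexagonal trellis kernel (CFF =", x$cff, ")\n")
  cat("weights / ", x$cff, ":\n", sep = "")
  print(x$weights)
  cat("DC gain:", format(x$gain, digits = 4), "\n")
  invisible(x)
}

#' @export
as.matrix.vht_kernel <- function(x, ...) x$weights
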