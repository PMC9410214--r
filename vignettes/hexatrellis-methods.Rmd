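---
title: "Methods: hexagonal-trellis filtering of blood-smear images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hexagonal-trellis filtering of blood-smear images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexatrellis)
```

This vignette is the package's own account of the science it implements: the
model and its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, the numerical conventions, and the
design decisions that were genuinely open. It states no empirical result
that the test suite or the acceptance script does not itself compute.

## 1. The virtual hexagonal trellis kernel

Hexagonal sampling gives every pixel six equidistant neighbors, which is
attractive for isotropic averaging, but cameras deliver square grids and
resampling onto a true hexagonal raster loses information. The construction
implemented here simulates the hexagonal neighborhood *on* the square grid,
without shifting or resampling any real pixel.

In a 3×3 neighborhood, label the corners `N1..N4`, the edge pixels `R1`
(left), `R2` (top centre), `R3` (bottom centre), `R4` (right), and the
centre `C1`. Four *virtual pixels* are placed at the midpoints between each
corner and the centre, valued by linear interpolation:

$$V_k = \frac{N_k + C_1}{2}.$$

The hexagonal neighborhood is then the seven-sample set
$\{V_1, V_2, R_1, C_1, R_4, V_3, V_4\}$ — the two vertical edge pixels are
dropped — and the filter replaces the centre with the seven-sample mean.
Substituting the $V_k$ and clearing denominators:

$$f'(C_1) = \frac{1}{14}\,\bigl(N_1 + N_2 + N_3 + N_4 + 2R_1 + 2R_4 + 6C_1\bigr),$$

i.e. the integer mask `[[1,0,1],[2,6,2],[1,0,1]]` over the divisor 14.
`derive_kernel()` performs this substitution symbolically at run time
(rational coefficients over the nine grid symbols) rather than returning a
constant, so each coefficient — centre 6, horizontal edges 2, vertical edges
0, corners 1, seven nonzero entries — is checkable against the derivation
itself.

The divisor is exposed as the *constant filter factor* (CFF). The weights
sum to 14, so the DC gain is `14/cff`: CFF below 14 brightens and saturates,
above 14 darkens, and exactly 14 preserves flat regions. The evaluation
protocol sweeps CFF over 7–19 and scores each output against the pre-filter
image; CFF 14 is the distortion minimum by construction. The CLI constrains
CFF to 7–19 unless `--allow-any-cff` is passed, while the library accepts
any positive integer.

A note on geometry: dropping the *vertical* rather than horizontal edge
pixels is taken from the construction as published; nothing in the midpoint
geometry forces that orientation, and the package preserves it as a
convention (row 1 = `N1 R2 N2`, row 2 = `R1 C1 R4`, row 3 = `N3 R3 N4`).

## 2. Convolution contract

`filter_image()` slides the kernel with stride 1 in both axes. Because the
mask is symmetric under 180° rotation, convolution and correlation coincide
(the suite asserts this). Two contracts the published description leaves
open are made explicit:

* **Border** — `replicate` (default), `reflect`, or `zero` padding, so the
  output always has the input's dimensions.
* **Rounding** — all arithmetic is exact integer arithmetic; for a weighted
  sum $s$ the quotient $s/\mathrm{cff}$ is rounded by `floor`, `half_up`
  (default), or `ceil`, computed as integer divisions
  (`(2s + cff) %/% (2 cff)` for half-up) so no floating-point tie-breaking
  can enter.

The rounding mode matters for fidelity: the single-patch worked example that
accompanies the construction has exact sum $59/14 \approx 4.21$ yet is
published as 5. Only ceiling rounding reproduces that value. Whether the
original authors used ceiling, a different normalizer, or made a
transcription slip is not decidable from the text, so the package defaults
to `half_up` for general use and uses `ceil` as the published-fidelity mode;
the acceptance target asserts the ceiling behavior.

## 3. Preprocessing chain

Stained-smear crops have a bright background and a dark, low-contrast cell
interior. The chain is: crop/resize (bilinear, or nearest by flag) →
complement (`v -> 255 - v`) → dehaze → inverse complement → grayscale
(BT.601 weights 0.299/0.587/0.114, rounded half-up). Dehazing runs on the
complemented image by default (`complement_chain = TRUE`) because the
dark-channel prior underlying it expects dark scene content; the flag exists
because the published pipeline is ambiguous on this point.

Dehazing inverts the scattering model $I = J\,t + A\,(1-t)$:

1. **Atmospheric light** $A$: per-channel mean of the pixels in the top
   0.1% of the dark channel (`atmos_quantile`), or an explicit value via
   `dehaze_params(atmos = ...)` when the haze source is known. The published
   description names $A$ but gives no estimator.
2. **Transmission** $t = 1 - \mathrm{dark}(I/A)$, clipped to $[0,1]$, where
   `dark()` is the patchwise minimum over channels (`patch_size = 15`).
3. **Restoration** $J = (I - A)/\max(t, t_{\mathrm{floor}}) + A$ with
   `t_floor = 0.1` limiting amplification, then optional gamma correction
   (`gamma = 1`, i.e. off, by default) and 8-bit clipping.

The restoration equation as published ($C_m = H_i - \gamma\max(T,t_i) +
\gamma$) is not the inverse of any stated forward model; the package
implements the standard scattering inverse above, which the cited dehazing
literature uses, and keeps $\gamma$ as an optional post-correction.

**When is this a faithful inversion?** Only where the dark-channel prior
holds for the underlying scene — some near-zero channel minimum in every
patch — and $A$ is known or identifiable. The test suite therefore checks
the quantitative round trip (`dehaze(add_haze(J, t, A))`, MAE ≤ 5 for
$t \ge 0.3$) on random scenes constructed to satisfy the prior exactly, with
$A$ passed to `dehaze_params()` — the forward model inverted under its own
assumptions. On the synthetic smear fixtures the same round trip does *not*
reach MAE ≤ 5, and cannot: the bright pinkish background violates the prior
everywhere (its dark channel is ≈ 200, not ≈ 0), and under spatially
constant transmission no pixel is haze-opaque, so $A$ is not identifiable
from the image at all. Even the best estimator in this family — $A$ equal to
the hazed background — leaves $(1-t)\lvert A - J_{bg}\rvert \approx 5.3$
mean error on the background alone, before the floored transmission map
inflates the cell region. One acceptance test asserts the smear-fixture
round trip anyway, faithfully to its stated protocol, and is expected to
fail; it is kept red deliberately rather than weakened, as a precise record
of what blind dehazing does and does not deliver on this class of imagery.
On smears, dehazing is a contrast amplifier for the cell interior, not a
calibrated restoration — which is exactly its role in the enhancement chain.

## 4. Quality metrics

All metrics operate on 8-bit grayscale matrices.

* **MSE** uses the squared difference (the published formula prints no
  exponent, but PSNR presupposes the square).
* **PSNR** $= 10\log_{10}(255^2/\mathrm{MSE})$, capped at 100 dB when
  MSE = 0 so reports stay numeric; the stray factor in the published
  formula is treated as a typesetting artifact.
* **SSIM**: mean of the local map in sliding Gaussian windows (11×11,
  $\sigma = 1.5$, the de-facto standard, exposed as arguments) with
  $C_1 = (0.01\cdot255)^2$, $C_2 = (0.03\cdot255)^2$.
* **NCC** $= \sum O R / \sum O^2$ and **NAE** $= \sum|O-R| / \sum O$,
  normalized by the reference; an all-zero reference is rejected explicitly.
* **Entropy**: base-2 Shannon entropy of the 256-bin histogram.
* **EME**: the image is tiled into 8×8-pixel blocks (trailing partial
  blocks included; the block counts $k_1 k_2$ follow from the image size)
  and $20\log_{10}((I_{\max}+\varepsilon)/(I_{\min}+\varepsilon))$ is
  averaged over blocks, $\varepsilon = 10^{-4}$ guarding zero minima. The
  "max over a class of orthogonal transforms" that the published definition
  mentions is not exercised in any of its tables and is not implemented.
* **Alpha rooting**: 2-D DFT, phase preserved, each magnitude replaced by
  its $\alpha$-th root normalized to keep the DC component fixed,
  $F' = F\,(|F|/|F_{DC}|)^{1/\alpha - 1}$; the real part of the inverse
  transform is min–max rescaled to $[0,255]$ only if it leaves the 8-bit
  range, so $\alpha = 1$ is an exact identity. The textbook map
  $|F|^\alpha$ *boosts* high frequencies for $\alpha < 1$ and makes
  blockwise contrast fall as $\alpha$ rises — the opposite of the monotone
  EME-vs-$\alpha$ behavior reported for this enhancement family, which the
  published account states only as a table, not a formula. The literal
  $\alpha$-th-root convention reproduces the reported direction (EME
  nondecreasing in $\alpha$, largest above 1), and the suite asserts that
  trend on the synthetic fixture.

Comparator filters: global histogram equalization (CDF remapping), the 3×3
box mean (the square-lattice ancestor of the hexagonal mask), and a locally
adaptive 3×3 Wiener filter with the noise floor estimated as the mean local
variance. One point of principle: discrete equalization is a deterministic
intensity LUT, so it can merge histogram bins but never split them — output
entropy mathematically cannot exceed input entropy. The property the suite
asserts is the one equalization actually guarantees: the intensity CDF moves
closer to uniform (Kolmogorov distance shrinks) and intensity spread grows.

## 5. The synthetic smear world

`generate_wbc_image()` draws one leukocyte per frame on a 240×320 RGB
raster (the acquisition convention of the smear datasets this emulates):
flat background (230, 200, 210), elliptical cytoplasm (200, 160, 200) with
the semi-major axis drawn from 45–60 px (a WBC fills a good fraction of a
cell-centred crop), a darker nucleus (90, 50, 130) built from 1–5
overlapping lobe discs (1 emulates lymphocyte/monocyte morphology, 2–5
neutrophil/eosinophil lobes), ~25 small platelet speckles, Gaussian blur
($\sigma = 1$ px, optical softness), and additive Gaussian noise
($\sigma = 4$ levels, sensor noise). The palette mimics a Giemsa stain and
is a fixture convention, not a measured value. `add_haze()` overlays the
scattering model with spatially constant $t$ (default 0.6) and light
(220, 220, 220); constant $t$ is sufficient to exercise the dehazing
equations and keeps the invertible-case round trip tight, with a per-pixel
$t$ field left as an extension point. Everything is deterministic per seed
(`withr::with_seed`), and the generator is first-class, tested code.

What a green test on this world establishes: the algebra and contracts of
every stage (kernel, convolution, metrics, drivers) and the qualitative
behavior of the enhancement chain. What it does not establish: performance
on real stained smears — no chromatin texture, staining variability,
illumination gradients, overlapping cells, or focus artifacts are modelled —
nor any of the dataset-level metric values reported for real WBC
collections, which depend on images this package does not ship.

## 6. Numerical choices and degenerate inputs

* Pixel arithmetic in the convolution path is exact integer arithmetic;
  intensities are validated into $[0,255]$ at every public boundary.
* `dehaze()` returns a constant image unchanged with a warning (no
  transmission information exists); equalization of a constant image is the
  identity; EME of a constant image is 0 by the $\varepsilon$-guard.
* Netpbm is the raster interchange format (PGM/PPM, ASCII and binary);
  inputs with `maxval != 255` are linearly rescaled to 8 bits with a
  warning. PNG/TIFF/BMP are out of scope here to keep the package free of
  binary-format dependencies.
* Resampling is bilinear with pixel-centre alignment (identity when sizes
  match), nearest-neighbor by flag.
* CSV is the canonical output of the experiment drivers; every run with a
  fixed configuration and seed is bit-reproducible (asserted).

## 7. Known limitations

* Blind atmospheric-light estimation is unreliable on bright-field
  microscopy (Section 3); supply `atmos` when the haze source is known.
* Only 3×3 hexagonal-trellis kernels are provided; larger trellises and
  true hexagonal resampling are out of scope by design.
* The no-reference learned quality scores (BRISQUE, NIQE, BIQI) are not
  implemented: they require pretrained natural-scene models, which are
  external artifacts rather than mathematics.
* EME depends strongly on block size and $\varepsilon$; comparisons are
  only meaningful at fixed settings.
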