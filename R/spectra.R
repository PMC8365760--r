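# Frequency-domain core: forward/inverse transforms, radial frequency
# grids in cycles per image, and the cycles-per-degree conversion.
#
# Transform normalization is fixed throughout the package:
# unnormalized forward DFT, 1/(H*W) inverse. Under this convention the
# amplitude at the zero-frequency bin equals H*W times the mean pixel
# value, and Parseval reads sum((x - mean)^2) = sum(amp[-DC]^2)/(H*W).

#' Decompose an image into amplitude and phase spectra
#'
#' Forward 2-D discrete Fourier transform of a grayscale image,
#' returned as separate amplitude and phase grids (a `"Spectrum"`
#' object). Color images must be decomposed one channel at a time; the
#' degradation operators handle channels internally.
#'
#' @param image numeric matrix (H x W), finite values.
#' @return an object of class `Spectrum`: a list with `amplitude`
#'   (non-negative H x W grid), `phase` (radians in (-pi, pi]),
#'   `height_px`, `width_px`.
#' @seealso [recompose_image()], [frequency_grid()]
#' @examples
#' sp <- decompose_image(matrix(runif(64, 0, 255), 8, 8))
#' sp$amplitude[1, 1] / (8 * 8) # mean pixel value
#' @export
decompose_image <- function(image) {
  if (length(dim(image)) == 3L)
    stop("decompose_image() takes a single channel; see per-channel operators")
  check_image(image)
  F <- stats::fft(image)
  structure(
    list(amplitude = Mod(F), phase = Arg(F),
         height_px = nrow(image), width_px = ncol(image)),
    class = "Spectrum"
  )
}

#' Recompose an image from amplitude and phase spectra
#'
#' Inverse transform of `amplitude * exp(1i * phase)`. The result of a
#' valid (Hermitian-symmetric) spectrum is real; an imaginary residue
#' above `1e-6` of the image dynamic range signals a malformed phase
#' grid and raises an error.
#'
#' @param spec a `Spectrum` object (see [decompose_image()]).
#' @return numeric H x W matrix.
#' @export
recompose_image <- function(spec) {
  stopifnot(inherits(spec, "Spectrum"))
  if (any(spec$amplitude < 0)) stop("Spectrum amplitude must be non-negative")
  n <- spec$height_px * spec$width_px
  z <- stats::fft(spec$amplitude * exp(1i * spec$phase), inverse = TRUE) / n
  re <- Re(z)
  dyn <- diff(range(re))
  if (dyn == 0) dyn <- max(abs(re), 1)
  if (max(abs(Im(z))) > 1e-6 * dyn)
    stop("spectrum is not Hermitian-symmetric: ",
         "inverse transform has a large imaginary part")
  re
}

#' Radial frequency grid in cycles per image
#'
#' Per-axis frequencies are computed in cycles per pixel (u/W
#' horizontally, v/H vertically), combined isotropically in pixel
#' space, and expressed in cycles per image by scaling with the image
#' height H:
#' \deqn{f(u, v) = H \sqrt{(u/W)^2 + (v/H)^2}.}
#' With this convention the Nyquist frequency is H/2 along both axes
#' and cycles per degree is simply cycles per image divided by the
#' display's vertical angular extent.
#'
#' @param height_px,width_px image dimensions in pixels (>= 2).
#' @return an object of class `FrequencyGrid`: list with `radial_cpi`
#'   (H x W grid, zero at DC) and `nyquist_cpi` (= H/2).
#' @examples
#' g <- frequency_grid(8, 8)
#' g$radial_cpi[1, 1]  # DC -> 0
#' g$nyquist_cpi       # 4
#' @export
frequency_grid <- function(height_px, width_px) {
  if (height_px < 2 || width_px < 2) stop("dimensions must be >= 2")
  fy <- 0:(height_px - 1)
  fy <- ifelse(fy > height_px / 2, fy - height_px, fy)
  fx <- 0:(width_px - 1)
  fx <- ifelse(fx > width_px / 2, fx - width_px, fx)
  radial <- height_px * sqrt(outer((fy / height_px)^2, (fx / width_px)^2, "+"))
  structure(list(radial_cpi = radial, nyquist_cpi = height_px / 2),
            class = "FrequencyGrid")
}

#' Convert cycles per image to cycles per degree
#'
#' A stimulus spanning `vertical_extent_deg` degrees of visual angle
#' maps a frequency of `f_cpi` cycles per image to
#' `f_cpi / vertical_extent_deg` cycles per degree. With an 11.6
#' degree display this reproduces the conventional cpd values for
#' typical filter cutoffs (e.g. 120.68 cpi -> 10.40 cpd).
#'
#' @param f_cpi frequency in cycles per image (vector ok).
#' @param vertical_extent_deg vertical extent of the stimulus in
#'   degrees of visual angle (> 0).
#' @return frequency in cycles per degree, unrounded.
#' @examples
#' round(cpi_to_cpd(c(120.68, 64), 11.6), 2) # 10.40, 5.52
#' @export
cpi_to_cpd <- function(f_cpi, vertical_extent_deg) {
  if (!is.numeric(vertical_extent_deg) || vertical_extent_deg <= 0)
    stop("vertical_extent_deg must be positive")
  f_cpi / vertical_extent_deg
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: %d x %d, DC amplitude %.4g (mean pixel %.4g)\n",
              x$height_px, x$width_px, x$amplitude[1, 1],
              x$amplitude[1, 1] / (x$height_px * x$width_px)))
  invisible(x)
}

#' @export
print.FrequencyGrid <- function(x, ...) {
  cat(sprintf("FrequencyGrid: %d x %d, Nyquist %.4g cpi\n",
              nrow(x$radial_cpi), ncol(x$radial_cpi), x$nyquist_cpi))
  invisible(x)
}
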