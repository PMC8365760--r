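#' scenedegrade: spatial-frequency degradation and observer comparison
#'
#' Frequency-domain stimulus degradation (band filtering, phase
#' scrambling, whitening, luminance standardization), Weibull
#' psychometric fitting with bootstrap thresholds, and accuracy /
#' agreement ratio statistics for comparing two classifiers, plus a
#' synthetic-data module that makes the whole pipeline runnable
#' without external images or participants.
#'
#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, restores. All
#' stochastic operators in the package route their randomness through
#' this helper so they never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible substream seed
#'
#' Maps a master seed plus an arbitrary string tag (e.g. a stimulus
#' id, or "bootstrap/3") to an integer seed in `[0, 2^31 - 2]`. The
#' mapping is a small multiplicative hash, fixed so manifests are
#' stable across platforms and sessions.
#'
#' @param master integer master seed.
#' @param ... character/numeric fragments identifying the substream.
#' @return a single integer seed.
#' @examples
#' derive_seed(42, "phase", "img001")
#' @export
derive_seed <- function(master, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- as.double(master %% 2147483647)
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' @keywords internal
#' @noRd
is_image <- function(x) {
  is.numeric(x) && (length(dim(x)) %in% c(2L, 3L))
}

#' @keywords internal
#' @noRd
check_image <- function(x, what = "image") {
  if (!is_image(x)) stop(what, " must be a numeric matrix or H x W x C array")
  d <- dim(x)
  if (any(d[1:2] < 2)) stop(what, " must be at least 2 x 2 pixels")
  if (!all(is.finite(x))) stop(what, " contains non-finite pixel values")
  invisible(x)
}

#' Apply a matrix operator to each channel of an image
#' @keywords internal
#' @noRd
per_channel <- function(image, fun) {
  if (length(dim(image)) == 2L) return(fun(image))
  out <- image
  for (ch in seq_len(dim(image)[3])) out[, , ch] <- fun(image[, , ch])
  out
}

#' Per-pixel luminance (channel mean) of an image
#' @keywords internal
#' @noRd
luminance_of <- function(image) {
  if (length(dim(image)) == 2L) image
  else apply(image, c(1, 2), mean)
}

#' Radially averaged amplitude spectrum
#'
#' Averages the amplitude spectrum of an image within annuli of one
#' cycle-per-image width, the standard diagnostic for the spectral
#' slope of natural images.
#'
#' @param image numeric matrix (grayscale); RGB arrays are reduced to
#'   their per-pixel channel mean first.
#' @return data.frame with columns `f_cpi` (annulus center) and
#'   `amplitude` (mean amplitude), DC excluded.
#' @export
radial_amplitude <- function(image) {
  img <- luminance_of(image)
  check_image(img)
  spec <- decompose_image(img)
  grid <- frequency_grid(nrow(img), ncol(img))
  bin <- round(grid$radial_cpi)
  keep <- bin > 0
  amp <- tapply(spec$amplitude[keep], bin[keep], mean)
  data.frame(f_cpi = as.numeric(names(amp)), amplitude = as.numeric(amp),
             row.names = NULL)
}

#' Log-log slope of the radial amplitude spectrum
#'
#' Regresses log amplitude on log radial frequency between two
#' fractions of the Nyquist frequency. A 1/f image has slope near -1;
#' a whitened image has slope near 0.
#'
#' @param image numeric matrix or RGB array.
#' @param band numeric length-2, passband as fractions of Nyquist
#'   (default `c(0.1, 0.6)`).
#' @return slope (a single number).
#' @export
spectral_slope <- function(image, band = c(0.1, 0.6)) {
  ra <- radial_amplitude(image)
  ny <- nrow(luminance_of(image)) / 2
  keep <- ra$f_cpi >= band[1] * ny & ra$f_cpi <= band[2] * ny &
    ra$amplitude > 0
  if (sum(keep) < 3) stop("too few radial bins in the requested band")
  unname(stats::coef(stats::lm(log(ra$amplitude[keep]) ~
                                 log(ra$f_cpi[keep])))[2])
}

#' Rank-based AUC of a score separating two classes
#' @keywords internal
#' @noRd
rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Read an 8-bit raster image as a 0-255 float array
#'
#' PNG and TIFF are supported (TIFF requires the `tiff` package).
#' Gray images come back as a matrix, color images as an H x W x 3
#' array; an alpha channel, if present, is dropped.
#'
#' @param path file path.
#' @return numeric matrix or array on a 0-255 scale.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) x <- x[, , 1:3]
  if (length(dim(x)) == 3L && dim(x)[3] == 2L) x <- x[, , 1]
  x * 255
}

#' Write a 0-255 float image to an 8-bit PNG
#'
#' Values are clipped to `[0, 255]` and quantized on write;
#' quantization is deliberately the last step so analyses can run on
#' the pre-quantization float image.
#'
#' @param image numeric matrix or H x W x 3 array, 0-255 scale.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_image(image)
  x <- pmin(pmax(image / 255, 0), 1)
  png::writePNG(x, path)
  invisible(path)
}
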