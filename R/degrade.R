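# Stimulus degradation operators: band filters with a parabolic
# falloff over three octaves, weighted mean phase scrambling, spectral
# whitening, and the two luminance renormalizations. All operators
# work in float on a 0-255 scale and return unnormalized floats;
# renormalize and quantize afterwards (see build_stimulus_set()).

#' Band-filter parameters
#'
#' A low- or high-pass spatial-frequency filter is specified by its
#' full-attenuation frequency `F1` (cycles per image). The passband
#' edge `F0` sits exactly three octaves away: `F0 = F1/8` for lowpass
#' and `F0 = 8*F1` for highpass, so `|log2(F1/F0)| = 3`.
#'
#' @param kind `"lowpass"` or `"highpass"`.
#' @param F1 full-attenuation frequency in cycles per image (> 0).
#' @return an object of class `FilterParams` with fields `kind`, `F1`,
#'   `F0`.
#' @examples
#' filter_params("lowpass", 64)$F0   # 8
#' filter_params("highpass", 10.67)$F0 # 85.36
#' @export
filter_params <- function(kind = c("lowpass", "highpass"), F1) {
  kind <- match.arg(kind)
  if (!is.numeric(F1) || length(F1) != 1L || F1 <= 0)
    stop("F1 must be a single positive frequency in cycles per image")
  F0 <- if (kind == "lowpass") F1 / 8 else F1 * 8
  structure(list(kind = kind, F1 = F1, F0 = F0), class = "FilterParams")
}

#' Scalar gain of a band filter at a radial frequency
#'
#' Frequencies inside the passband pass with gain 1; beyond the
#' passband edge `F0` the amplitude rolls off as a parabola in
#' octaves, reaching 0 exactly at `F1`, three octaves away:
#' \deqn{g = 1 - (x/3)^2, \quad x = |\log_2(f / F_0)| \in (0, 3).}
#' For a highpass filter the mirror-image parabola applies below
#' `F0`. The gain at f = 0 for a highpass filter is 0 by this
#' definition; `apply_band_filter()` exempts the DC bin so that the
#' image mean survives for the subsequent renormalization.
#'
#' @param f radial frequency in cycles per image (vector or grid,
#'   >= 0).
#' @param params a [filter_params()] object.
#' @return gain in `[0, 1]`, same shape as `f`.
#' @examples
#' p <- filter_params("lowpass", 64)
#' filter_gain(c(p$F0, p$F0 * 2^1.5, p$F1), p) # 1, 0.75, 0
#' @export
filter_gain <- function(f, params) {
  stopifnot(inherits(params, "FilterParams"))
  if (any(f < 0)) stop("frequencies must be non-negative")
  g <- array(0, dim = if (is.null(dim(f))) length(f) else dim(f))
  if (params$kind == "lowpass") {
    x <- ifelse(f > 0, log2(f / params$F0), -Inf)
    g[] <- ifelse(x <= 0, 1, ifelse(x >= 3, 0, 1 - (x / 3)^2))
  } else {
    x <- ifelse(f > 0, log2(params$F0 / f), Inf)
    g[] <- ifelse(x <= 0, 1, ifelse(x >= 3, 0, 1 - (x / 3)^2))
  }
  if (is.null(dim(f))) as.numeric(g) else g
}

#' Apply a low- or high-pass spatial-frequency filter
#'
#' Multiplies the amplitude spectrum of each channel by
#' [filter_gain()] evaluated on the radial frequency grid; phase is
#' untouched. The DC bin always passes (gain 1) so the image mean is
#' preserved for renormalization.
#'
#' @param image numeric matrix or H x W x C array, 0-255 float scale.
#' @param params a [filter_params()] object.
#' @return filtered image (unnormalized float, same shape).
#' @export
apply_band_filter <- function(image, params) {
  stopifnot(inherits(params, "FilterParams"))
  check_image(image)
  d <- dim(image)
  grid <- frequency_grid(d[1], d[2])
  gain <- filter_gain(grid$radial_cpi, params)
  gain[1, 1] <- 1
  per_channel(image, function(ch) {
    spec <- decompose_image(ch)
    spec$amplitude <- spec$amplitude * gain
    recompose_image(spec)
  })
}

#' Weighted mean phase scrambling
#'
#' Mixes the original phase spectrum with the phase of a random-noise
#' field, circularly: the new phase at each bin is the argument of
#' \deqn{(1 - w)\,e^{i\phi_{orig}} + w\,e^{i\phi_{noise}},}
#' and is recombined with the *original* amplitude spectrum, which is
#' therefore preserved exactly. The noise phase field is the phase of
#' the DFT of white Gaussian noise, so it is uniform on (-pi, pi] and
#' Hermitian-symmetric by construction; for color images one noise
#' field is shared across channels.
#'
#' @param image numeric matrix or H x W x C array.
#' @param w noise-phase weight in `[0, 1]`: 0 returns the original
#'   image, 1 retains only the amplitude spectrum.
#' @param seed integer seed for the noise field; the same seed gives a
#'   bit-identical output.
#' @return phase-scrambled image (unnormalized float).
#' @export
phase_scramble <- function(image, w, seed) {
  if (!is.numeric(w) || length(w) != 1L || w < 0 || w > 1)
    stop("phase weight w must lie in [0, 1]")
  check_image(image)
  d <- dim(image)
  # namespaced substream so an identical integer seed never reuses the
  # random field of another stochastic operator
  noise <- with_seed(derive_seed(seed, "phase-noise"),
                     matrix(stats::rnorm(d[1] * d[2]), d[1], d[2]))
  phi_noise <- Arg(stats::fft(noise))
  per_channel(image, function(ch) {
    spec <- decompose_image(ch)
    mix <- (1 - w) * exp(1i * spec$phase) + w * exp(1i * phi_noise)
    # near-cancelled mixtures (phases ~pi apart at w ~ 0.5) amplify the
    # rounding asymmetry of the two FFT phase grids, so Hermitian
    # antisymmetry is re-imposed by construction
    spec$phase <- hermitian_phase(Arg(mix))
    recompose_image(spec)
  })
}

#' Impose Hermitian antisymmetry on a phase grid
#'
#' Copies each canonical bin's phase, negated, onto its frequency-
#' negated partner and snaps self-conjugate bins (DC and the Nyquist
#' bins of even dimensions) to 0 or pi, so that any amplitude grid
#' combined with the result inverts to a real image.
#'
#' @param ph phase matrix in radians.
#' @return antisymmetric phase matrix.
#' @keywords internal
#' @noRd
hermitian_phase <- function(ph) {
  h <- nrow(ph); w <- ncol(ph)
  ri <- c(1L, h:2L); ci <- c(1L, w:2L)
  lin <- matrix(seq_len(h * w), h, w)
  linc <- lin[ri, ci]
  conj_ph <- -ph[ri, ci]
  out <- ph
  noncanon <- lin > linc
  out[noncanon] <- conj_ph[noncanon]
  selfc <- lin == linc
  out[selfc] <- ifelse(cos(ph[selfc]) >= 0, 0, pi)
  out
}

#' Spectral whitening gain
#' @keywords internal
#' @noRd
whitening_gain <- function(f, nyquist, power = 4) {
  ifelse(f > 0, (f / nyquist) * exp(1 - (f / nyquist)^power), 1)
}

#' Whiten an image (flatten its amplitude spectrum)
#'
#' Multiplies the amplitude spectrum by a gain that increases with
#' spatial frequency up to the Nyquist frequency,
#' \deqn{W(f) = (f/f_N)\, e^{1 - (f/f_N)^p},}
#' with `p = 4` by default. The linear rise in f cancels the 1/f
#' amplitude falloff of natural images, flattening the spectrum; the
#' exponential guard rolls the gain back near Nyquist so that
#' whitening does not amplify high-frequency noise. The DC bin is
#' exempt (gain 1), so the image mean is preserved.
#'
#' @param image numeric matrix or H x W x C array.
#' @param power exponent of the near-Nyquist guard (default 4). The
#'   analytic form of the gain is a package choice; `power` is exposed
#'   so alternatives can be explored.
#' @return whitened image (unnormalized float).
#' @export
whiten <- function(image, power = 4) {
  check_image(image)
  d <- dim(image)
  grid <- frequency_grid(d[1], d[2])
  gain <- whitening_gain(grid$radial_cpi, grid$nyquist_cpi, power)
  per_channel(image, function(ch) {
    spec <- decompose_image(ch)
    spec$amplitude <- spec$amplitude * gain
    recompose_image(spec)
  })
}

#' Standardize image luminance to a target mean and SD
#'
#' Affinely rescales the image so that the pixel intensity mean and
#' standard deviation hit the targets (defaults 128 and 72.11, the
#' usual balancing of natural-scene stimulus sets), then clips to
#' `[0, 255]`. Statistics are computed on the per-pixel channel mean
#' for color images and the same affine map is applied to every
#' channel. When nothing clips, the output statistics equal the
#' targets to machine precision and the operation is idempotent.
#'
#' @param image numeric matrix or H x W x C array.
#' @param target_mean,target_sd targets on the 0-255 scale.
#' @return standardized image in `[0, 255]`.
#' @export
normalize_mean_sd <- function(image, target_mean = 128, target_sd = 72.11) {
  check_image(image)
  lum <- luminance_of(image)
  s <- stats::sd(lum)
  if (s == 0) stop("constant image: SD is undefined for rescaling")
  a <- target_sd / s
  b <- target_mean - a * mean(lum)
  pmin(pmax(a * image + b, 0), 255)
}

#' Stretch an image to span the full 0-255 range
#'
#' Linear map sending the minimum pixel value (over all channels) to 0
#' and the maximum to 255. This is the renormalization applied to each
#' degraded stimulus before display.
#'
#' @param image numeric matrix or H x W x C array, non-constant.
#' @return image spanning `[0, 255]`.
#' @export
stretch_full_range <- function(image) {
  check_image(image)
  lo <- min(image); hi <- max(image)
  if (hi == lo) stop("constant image: cannot stretch a zero range")
  (image - lo) / (hi - lo) * 255
}

#' Degradation level presets
#'
#' The packaged parameter grids. The `"human"` preset holds the four
#' levels per degradation type shown to human observers; the `"cnn"`
#' preset the fifteen levels per type used to test artificial
#' classifiers (the four human levels are a subset of each fifteen).
#' Filter levels are F1 values in cycles per image; phase-scrambling
#' levels are noise-phase weights in `[0, 1]`.
#'
#' @param set `"human"` or `"cnn"`.
#' @return named list with elements `lowpass`, `highpass`,
#'   `phase_scramble`.
#' @examples
#' degradation_presets("human")$highpass
#' @export
degradation_presets <- function(set = c("human", "cnn")) {
  set <- match.arg(set)
  if (set == "human") {
    list(
      lowpass = c(5.66, 9.19, 14.93, 64),
      highpass = c(120.68, 85.33, 60.34, 10.67),
      phase_scramble = c(0.70, 0.65, 0.60, 0.40)
    )
  } else {
    list(
      lowpass = c(2.14, 3.48, 5.66, 9.19, 14.93, 24.25, 39.40, 64.00,
                  103.97, 168.90, 274.37, 445.72, 724.08, 1176.27, 1910.85),
      highpass = c(170.67, 120.68, 85.33, 60.34, 42.67, 30.17, 21.33,
                   15.09, 10.67, 7.54, 5.33, 3.77, 2.67, 1.89, 1.33),
      phase_scramble = seq(85, 15, by = -5) / 100
    )
  }
}

#' Apply one degradation to one image
#'
#' Dispatcher used by [build_stimulus_set()] and the pipeline: applies
#' the requested operator in float, then stretches the result to the
#' full 0-255 range (the per-stimulus renormalization). Whitening is
#' not a degradation level; it is available here for preprocessing
#' sweeps with `kind = "whiten"` (its `level` is ignored).
#'
#' @param image numeric matrix or array, 0-255 scale.
#' @param kind one of `"lowpass"`, `"highpass"`, `"phase_scramble"`,
#'   `"whiten"`.
#' @param level F1 in cycles per image for the filters, noise weight
#'   in `[0, 1]` for phase scrambling.
#' @param seed integer seed (used by phase scrambling only).
#' @param renormalize stretch the output to `[0, 255]` (default TRUE).
#' @return degraded image.
#' @export
degrade_image <- function(image, kind, level = NA, seed = 0L,
                          renormalize = TRUE) {
  out <- switch(kind,
    lowpass = apply_band_filter(image, filter_params("lowpass", level)),
    highpass = apply_band_filter(image, filter_params("highpass", level)),
    phase_scramble = phase_scramble(image, level, seed),
    whiten = whiten(image),
    stop("unknown degradation kind: ", kind)
  )
  if (renormalize) {
    # a filter level beyond the corner frequency of the grid removes
    # every non-DC component; the stimulus is legitimately a uniform
    # field, rendered mid-gray rather than range-stretched
    if (max(out) - min(out) < 1e-9) out[] <- 128
    else out <- stretch_full_range(out)
  }
  out
}

#' Build (or enumerate) a degraded stimulus set
#'
#' Crosses every input image with every requested degradation kind and
#' level, producing one stimulus per combination. Phase-scramble seeds
#' are derived deterministically from the master seed and the stimulus
#' identity, so re-running with the same master seed reproduces the
#' manifest and every pixel. With `out_dir = NULL` only the manifest
#' is returned (useful for enumerating a design); otherwise each
#' stimulus is written as an 8-bit PNG under `out_dir`.
#'
#' @param images named list of images (0-255 float), a character
#'   vector of file paths, or a character vector of bare ids
#'   (enumeration only).
#' @param kinds character vector of degradation kinds.
#' @param levels_per_kind named list mapping each kind to its level
#'   vector, e.g. [degradation_presets()].
#' @param seed master seed.
#' @param out_dir output directory for PNGs, or NULL to enumerate.
#' @return data.frame manifest with columns `stimulus_id`, `source`,
#'   `kind`, `level`, `seed`, `path`.
#' @examples
#' m <- build_stimulus_set(paste0("img", 1:4), c("lowpass", "highpass"),
#'                         degradation_presets("human"), seed = 1)
#' nrow(m) # 4 * 2 * 4
#' @export
build_stimulus_set <- function(images, kinds, levels_per_kind, seed,
                               out_dir = NULL) {
  if (length(images) == 0) stop("empty image list")
  ids <- names(images)
  if (is.null(ids)) {
    ids <- if (is.character(images)) {
      ifelse(file.exists(images), tools::file_path_sans_ext(basename(images)),
             images)
    } else sprintf("img%04d", seq_along(images))
  }
  if (anyDuplicated(ids)) stop("image ids must be unique")
  for (k in kinds) {
    lv <- levels_per_kind[[k]]
    if (is.null(lv) || length(lv) == 0)
      stop("no levels supplied for kind '", k, "'")
    if (k %in% c("lowpass", "highpass") && any(lv <= 0))
      stop("filter levels must be positive")
    if (k == "phase_scramble" && any(lv < 0 | lv > 1))
      stop("phase weights must lie in [0, 1]")
  }
  rows <- do.call(rbind, lapply(kinds, function(k) {
    expand.grid(source = ids, kind = k, level = levels_per_kind[[k]],
                stringsAsFactors = FALSE)
  }))
  rows$stimulus_id <- sprintf("%s_%s_%g", rows$source, rows$kind, rows$level)
  rows$seed <- vapply(rows$stimulus_id, function(s) derive_seed(seed, s),
                      integer(1))
  rows$path <- NA_character_
  rows <- rows[, c("stimulus_id", "source", "kind", "level", "seed", "path")]
  rownames(rows) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    get_img <- function(id) {
      i <- match(id, ids)
      x <- images[[i]]
      if (is.character(x)) read_image(x) else x
    }
    for (r in seq_len(nrow(rows))) {
      img <- get_img(rows$source[r])
      out <- degrade_image(img, rows$kind[r], rows$level[r], rows$seed[r])
      rows$path[r] <- file.path(out_dir, paste0(rows$stimulus_id[r], ".png"))
      write_image(out, rows$path[r])
    }
  }
  rows
}
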