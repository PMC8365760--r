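# Synthetic-data generators: 1/f natural-like images with two
# separable object categories, simulated Weibull observers (optionally
# pairs with shared per-image difficulty), deterministic crop
# augmentation, and a spectral-feature stand-in classifier. Together
# they let the degradation, fitting and comparison machinery run end
# to end without any external pictures, participants or networks.

#' Parameters for synthetic natural-like images
#'
#' Defaults mirror a typical natural-scene stimulus set: 323 x 431
#' pixel frames with a 1/f amplitude spectrum (spectral slope 1).
#' `class_signal` scales the class-specific geometry added by
#' [gen_two_class_set()], relative to the background's pixel SD.
#'
#' @param height_px,width_px image size in pixels.
#' @param spectral_slope amplitude falloff exponent (>= 0; 1 = pink).
#' @param class_signal relative amplitude of class structure (>= 0).
#' @return list of validated parameters.
#' @export
synthetic_image_params <- function(height_px = 323, width_px = 431,
                                   spectral_slope = 1, class_signal = 1) {
  if (spectral_slope < 0) stop("spectral_slope must be >= 0")
  if (class_signal < 0) stop("class_signal must be >= 0")
  if (height_px < 8 || width_px < 8) stop("images must be at least 8 x 8")
  list(height_px = height_px, width_px = width_px,
       spectral_slope = spectral_slope, class_signal = class_signal)
}

#' Generate a 1/f (pink-noise) image
#'
#' Builds the amplitude spectrum as `f^(-slope)` with the DC bin set
#' for mid-gray, attaches a uniform random Hermitian-symmetric phase
#' (the phase of the DFT of white noise), inverts, and standardizes
#' luminance to mean 128 and SD 72.11.
#'
#' @param params see [synthetic_image_params()].
#' @param seed integer seed; same seed, same image.
#' @return image matrix in `[0, 255]`.
#' @export
gen_pink_image <- function(params = synthetic_image_params(), seed = 1L) {
  h <- params$height_px; w <- params$width_px
  grid <- frequency_grid(h, w)
  amp <- ifelse(grid$radial_cpi > 0,
                grid$radial_cpi^(-params$spectral_slope), 0)
  amp[1, 1] <- h * w * 128
  noise <- with_seed(derive_seed(seed, "pink-phase"),
                     matrix(stats::rnorm(h * w), h, w))
  phi <- Arg(stats::fft(noise))
  spec <- structure(list(amplitude = amp, phase = phi,
                         height_px = h, width_px = w), class = "Spectrum")
  normalize_mean_sd(recompose_image(spec))
}

#' @keywords internal
#' @noRd
render_blobs <- function(h, w, n_blobs = 3) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  out <- matrix(0, h, w)
  for (j in seq_len(n_blobs)) {
    cy <- stats::runif(1, 0.2 * h, 0.8 * h)
    cx <- stats::runif(1, 0.2 * w, 0.8 * w)
    sg <- stats::runif(1, 0.08, 0.15) * min(h, w)
    sgn <- sample(c(-1, 1), 1)
    out <- out + sgn * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sg^2))
  }
  out
}

#' @keywords internal
#' @noRd
render_grid <- function(h, w) {
  period <- sample(6:12, 1)
  off_r <- sample.int(period, 1) - 1L
  off_c <- sample.int(period, 1) - 1L
  rows <- ((seq_len(h) + off_r) %% period) < 2
  cols <- ((seq_len(w) + off_c) %% period) < 2
  out <- outer(rows, cols, "|") * 1.0
  # one rectangle outline adds longer straight edges
  r0 <- sample.int(h %/% 3, 1); c0 <- sample.int(w %/% 3, 1)
  r1 <- r0 + h %/% 3; c1 <- c0 + w %/% 3
  out[r0:r1, c(c0, c1)] <- out[r0:r1, c(c0, c1)] + 1
  out[c(r0, r1), c0:c1] <- out[c(r0, r1), c0:c1] + 1
  out - mean(out)
}

#' Generate a labeled two-category synthetic image set
#'
#' Each image is a 1/f background plus class-specific geometry:
#' category A ("blob") adds a cluster of smooth Gaussian blobs, whose
#' energy sits at low radial frequencies; category B ("grid") adds
#' rectilinear line/edge structure, with energy at higher frequencies
#' and cardinal orientations. The two categories are therefore
#' separable both in the amplitude spectrum and in phase-dependent
#' geometry, so that filter and phase manipulations both have bite.
#' `class_signal = 0` makes the categories statistically identical.
#'
#' @param n_per_class images per category (>= 1).
#' @param params see [synthetic_image_params()].
#' @param seed master seed; per-image seeds are derived from it.
#' @return list with `images` (named list of matrices in `[0, 255]`),
#'   `labels` (0 = blob, 1 = grid) and a `manifest` data.frame
#'   (`image_id`, `label`, `seed`).
#' @export
gen_two_class_set <- function(n_per_class, params = synthetic_image_params(),
                              seed = 1L) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  n <- 2L * n_per_class
  ids <- sprintf("syn%04d", seq_len(n))
  labels <- rep(c(0L, 1L), n_per_class)
  seeds <- vapply(ids, function(i) derive_seed(seed, "image", i), integer(1))
  h <- params$height_px; w <- params$width_px
  images <- vector("list", n)
  names(images) <- ids
  for (i in seq_len(n)) {
    bg <- gen_pink_image(params, seed = seeds[i])
    if (params$class_signal > 0) {
      structure_img <- with_seed(derive_seed(seed, "structure", ids[i]), {
        if (labels[i] == 0L) render_blobs(h, w) else render_grid(h, w)
      })
      s <- stats::sd(structure_img)
      if (s > 0)
        bg <- bg + structure_img * (params$class_signal *
                                      stats::sd(bg) / s)
    }
    images[[i]] <- normalize_mean_sd(bg)
  }
  list(images = images, labels = labels,
       manifest = data.frame(image_id = ids, label = labels, seed = seeds,
                             stringsAsFactors = FALSE))
}

#' Deterministic crop augmentation
#'
#' Produces `n_versions` crops covering 80% of each image dimension,
#' on a fixed raster schedule: two vertical offsets (0% and 10% of the
#' height) crossed with five horizontal offsets (0, 5, 10, 15, 20% of
#' the width), row-major. The schedule is deterministic, so the output
#' list is identical on re-run.
#'
#' @param image numeric matrix or H x W x C array.
#' @param n_versions number of crops (<= 10 distinct positions).
#' @return list of cropped images, each `floor(0.8 H) x floor(0.8 W)`.
#' @export
crop_augment <- function(image, n_versions = 10) {
  check_image(image)
  d <- dim(image)
  ch <- floor(0.8 * d[1]); cw <- floor(0.8 * d[2])
  if (ch < 1 || cw < 1) stop("image too small for an 80% crop")
  offs <- expand.grid(col = round(c(0, 0.05, 0.10, 0.15, 0.20) * d[2]),
                      row = round(c(0, 0.10) * d[1]))
  offs$row <- pmin(offs$row, d[1] - ch)
  offs$col <- pmin(offs$col, d[2] - cw)
  offs <- unique(offs[, c("row", "col")])
  if (n_versions > nrow(offs))
    stop("n_versions exceeds the ", nrow(offs), " distinct crop positions")
  lapply(seq_len(n_versions), function(i) {
    r <- offs$row[i] + seq_len(ch)
    c <- offs$col[i] + seq_len(cw)
    if (length(d) == 2L) image[r, c] else image[r, c, , drop = FALSE]
  })
}

#' Simulated Weibull observer model
#'
#' One Weibull parameter set per degradation kind (guess rate fixed at
#' 0.5). `shared_difficulty_sd` is used by
#' [simulate_paired_observers()]: the SD of a per-image latent
#' difficulty, on the log-clarity scale, common to paired observers.
#'
#' @param alpha,beta,lambda named numeric vectors (one entry per
#'   degradation kind) or single values recycled over `kinds`.
#' @param kinds degradation kinds covered by the model.
#' @param shared_difficulty_sd latent difficulty SD (>= 0).
#' @return an `observer_model` list.
#' @export
observer_model <- function(alpha, beta = 3, lambda = 0.01,
                           kinds = c("lowpass", "highpass",
                                     "phase_scramble"),
                           shared_difficulty_sd = 0) {
  expand <- function(x) {
    if (!is.null(names(x))) return(x[kinds])
    stats::setNames(rep_len(x, length(kinds)), kinds)
  }
  a <- expand(alpha); b <- expand(beta); l <- expand(lambda)
  if (any(a <= 0) || any(b <= 0) || any(l < 0) || any(l + 0.5 >= 1))
    stop("invalid Weibull parameters")
  if (shared_difficulty_sd < 0) stop("shared_difficulty_sd must be >= 0")
  structure(list(alpha = a, beta = b, lambda = l, gamma = 0.5,
                 shared_difficulty_sd = shared_difficulty_sd),
            class = "observer_model")
}

#' @keywords internal
#' @noRd
observer_p_correct <- function(model, kind, clarity) {
  weibull_psy(clarity, model$alpha[[kind]], model$beta[[kind]],
              model$gamma, model$lambda[[kind]])
}

#' Simulate one observer's trial table
#'
#' Each design row (kind, level, n_trials) yields `n_trials` trials
#' whose probability of a correct response follows the observer's
#' Weibull at that clarity. True categories alternate evenly between
#' the two classes; the decision label is the true category when
#' correct and the other category otherwise.
#'
#' @param model an [observer_model()].
#' @param design data.frame with columns `kind`, `level`, `n_trials`.
#' @param seed integer seed.
#' @param observer_id label stored in the table.
#' @return a trial table: data.frame with columns `observer_id`,
#'   `stimulus_id`, `true_category`, `degradation_kind`, `level`,
#'   `decision`, `correct`.
#' @export
simulate_observer <- function(model, design, seed = 1L,
                              observer_id = "obs1") {
  stopifnot(inherits(model, "observer_model"))
  tabs <- with_seed(seed, {
    lapply(seq_len(nrow(design)), function(i) {
      kind <- design$kind[i]; level <- design$level[i]
      n <- design$n_trials[i]
      p <- observer_p_correct(model, kind, clarity_axis(kind, level))
      true_cat <- rep_len(c("animal", "vehicle"), n)
      correct <- stats::runif(n) < p
      decision <- ifelse(correct, true_cat,
                         ifelse(true_cat == "animal", "vehicle", "animal"))
      data.frame(observer_id = observer_id,
                 stimulus_id = sprintf("%s_%g_%04d", kind, level,
                                       seq_len(n)),
                 true_category = true_cat, degradation_kind = kind,
                 level = level, decision = decision, correct = correct,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, tabs)
}

#' Simulate a pair of observers with shared image difficulty
#'
#' Both observers see the same stimuli. Each stimulus carries a latent
#' difficulty `d_i ~ Normal(0, shared_difficulty_sd)` that multiplies
#' both observers' effective clarity by `exp(d_i)`; with
#' `shared_difficulty_sd = 0` the two observers' errors are
#' conditionally independent, giving the null model for the agreement
#' ratio.
#'
#' @param model_h,model_c [observer_model()]s for the two observers.
#' @param design data.frame with columns `kind`, `level`, `n_trials`.
#' @param shared_difficulty_sd latent difficulty SD on the
#'   log-clarity scale.
#' @param seed integer seed.
#' @return list of two aligned trial tables, `h` and `c`.
#' @export
simulate_paired_observers <- function(model_h, model_c, design,
                                      shared_difficulty_sd = 0, seed = 1L) {
  stopifnot(inherits(model_h, "observer_model"),
            inherits(model_c, "observer_model"))
  if (shared_difficulty_sd < 0) stop("shared_difficulty_sd must be >= 0")
  res <- with_seed(seed, {
    lapply(seq_len(nrow(design)), function(i) {
      kind <- design$kind[i]; level <- design$level[i]
      n <- design$n_trials[i]
      cl <- clarity_axis(kind, level)
      d <- stats::rnorm(n, 0, shared_difficulty_sd)
      cl_i <- cl * exp(d)
      true_cat <- rep_len(c("animal", "vehicle"), n)
      ids <- sprintf("%s_%g_%04d", kind, level, seq_len(n))
      mk <- function(model, obs) {
        p <- observer_p_correct(model, kind, cl_i)
        correct <- stats::runif(n) < p
        decision <- ifelse(correct, true_cat,
                           ifelse(true_cat == "animal", "vehicle",
                                  "animal"))
        data.frame(observer_id = obs, stimulus_id = ids,
                   true_category = true_cat, degradation_kind = kind,
                   level = level, decision = decision, correct = correct,
                   stringsAsFactors = FALSE)
      }
      list(h = mk(model_h, "human"), c = mk(model_c, "classifier"))
    })
  })
  list(h = do.call(rbind, lapply(res, `[[`, "h")),
       c = do.call(rbind, lapply(res, `[[`, "c")))
}

#' Spectral features of an image
#'
#' Log band-energy proportions in `n_bands` log-spaced radial annuli
#' between 1 cpi and Nyquist, plus two orientation-energy ratios
#' (cardinal vs total, horizontal vs vertical) over the upper half of
#' the spectrum. Proportions (of total non-DC energy) rather than
#' absolute energies keep the features bounded when a band filter
#' empties part of the spectrum, so a model trained on intact images
#' degrades gracefully on filtered ones.
#'
#' @param image numeric matrix or array (0-255 scale).
#' @param n_bands number of radial bands (default 8).
#' @return named numeric feature vector.
#' @export
extract_spectral_features <- function(image, n_bands = 8) {
  img <- luminance_of(image)
  h <- nrow(img); w <- ncol(img)
  A <- Mod(stats::fft(img - mean(img)))
  grid <- frequency_grid(h, w)
  f <- grid$radial_cpi; ny <- grid$nyquist_cpi
  edges <- exp(seq(log(1), log(ny), length.out = n_bands + 1))
  e2 <- A^2
  e_tot <- sum(e2[f > 0]) + 1e-12
  band <- vapply(seq_len(n_bands), function(b) {
    keep <- f >= edges[b] & f < edges[b + 1]
    log(sum(e2[keep]) / e_tot + 1e-6)
  }, numeric(1))
  fy <- 0:(h - 1); fy <- ifelse(fy > h / 2, fy - h, fy)
  fx <- 0:(w - 1); fx <- ifelse(fx > w / 2, fx - w, fx)
  ang <- atan2(matrix(fy / h, h, w), matrix(fx / w, h, w, byrow = TRUE))
  hi <- f > 0.25 * ny
  cardinal <- hi & (abs(sin(2 * ang)) < 0.45)
  horiz <- hi & (abs(sin(ang)) < 0.35)  # energy along the x frequency axis
  vert <- hi & (abs(cos(ang)) < 0.35)
  tot <- sum(e2[hi]) + 1e-12
  c(stats::setNames(band, paste0("band", seq_len(n_bands))),
    cardinal_ratio = sum(e2[cardinal]) / tot,
    hv_ratio = (sum(e2[horiz]) + 1e-12) / (sum(e2[vert]) + 1e-12))
}

#' Spectral-feature stand-in classifier
#'
#' A ridge-regularized logistic model on [extract_spectral_features()],
#' standing in for a fine-tuned network at desk scale: it is trained
#' on labeled images and scores new images in `[0, 1]`. Because its
#' features are amplitude-spectrum statistics, it is insensitive to
#' phase structure; the synthetic two-class set is partly separable by
#' amplitude alone, so this classifier stays above chance under full
#' phase scrambling (a documented difference from classifiers that use
#' spatial geometry).
#'
#' Deep networks owe much of their robustness to degraded inputs to
#' the invariances acquired in large-scale pretraining; a ten-feature
#' linear probe has no such prior, so `augment` optionally appends
#' degraded copies of each training image (random kind and level drawn
#' from the supplied grids) to the training set. Without augmentation
#' the probe collapses to chance under band filtering it never saw,
#' even when the filtered classes remain perfectly separable.
#'
#' @param train_images list of images; `train_labels` 0/1 vector.
#' @param train_labels 0/1 labels, both classes present.
#' @param test_images list of images to score.
#' @param lambda ridge penalty (default 0.05).
#' @param augment NULL, or a list with `levels_per_kind` (named list
#'   of degradation grids), `n_per_image` (degraded copies per
#'   training image, default 2) and `seed`.
#' @return numeric vector of scores in `[0, 1]`, one per test image.
#' @export
spectral_feature_classifier <- function(train_images, train_labels,
                                        test_images, lambda = 0.05,
                                        augment = NULL) {
  model <- train_spectral_classifier(train_images, train_labels,
                                     lambda = lambda, augment = augment)
  predict_scores(model, test_images)
}

#' Train the spectral-feature classifier
#'
#' The training half of [spectral_feature_classifier()]; the returned
#' model can score many stimulus sets without retraining.
#'
#' @inheritParams spectral_feature_classifier
#' @return a `spectral_classifier` model object.
#' @export
train_spectral_classifier <- function(train_images, train_labels,
                                      lambda = 0.05, augment = NULL) {
  if (length(unique(train_labels)) < 2)
    stop("training set must contain both classes")
  if (!is.null(augment)) {
    lpk <- augment$levels_per_kind
    n_aug <- if (is.null(augment$n_per_image)) 2L else augment$n_per_image
    aseed <- if (is.null(augment$seed)) 0L else augment$seed
    cells <- do.call(rbind, lapply(names(lpk), function(k)
      data.frame(kind = k, level = lpk[[k]], stringsAsFactors = FALSE)))
    extra <- list(); extra_lab <- integer(0)
    for (i in seq_along(train_images)) {
      pick <- with_seed(derive_seed(aseed, "augment-pick", i),
                        sample(nrow(cells), n_aug))
      for (j in pick) {
        extra[[length(extra) + 1L]] <- degrade_image(
          train_images[[i]], cells$kind[j], cells$level[j],
          derive_seed(aseed, "augment", i, j))
        extra_lab <- c(extra_lab, train_labels[i])
      }
    }
    train_images <- c(train_images, extra)
    train_labels <- c(train_labels, extra_lab)
  }
  X <- t(vapply(train_images, extract_spectral_features,
                numeric(length(extract_spectral_features(
                  train_images[[1]])))))
  fit <- glmnet::glmnet(X, factor(train_labels), family = "binomial",
                        alpha = 0, lambda = lambda, standardize = TRUE)
  structure(list(fit = fit, n_features = ncol(X)),
            class = "spectral_classifier")
}

#' Score images with a trained spectral classifier
#'
#' @param model a [train_spectral_classifier()] model.
#' @param images list of images to score.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict_scores <- function(model, images) {
  stopifnot(inherits(model, "spectral_classifier"))
  Xt <- t(vapply(images, extract_spectral_features,
                 numeric(model$n_features)))
  as.numeric(stats::predict(model$fit, Xt, type = "response"))
}
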