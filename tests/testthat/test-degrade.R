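test_that("filter parameters keep the three-octave edge relation", {
  presets <- degradation_presets("cnn")
  for (kind in c("lowpass", "highpass")) {
    for (F1 in presets[[kind]]) {
      p <- filter_params(kind, F1)
      expect_equal(abs(log2(p$F1 / p$F0)), 3)
    }
  }
  expect_error(filter_params("lowpass", 0), "positive")
  expect_error(filter_params("lowpass", -3), "positive")
})

test_that("filter gain has the right endpoints and parabola", {
  lp <- filter_params("lowpass", 64)
  expect_equal(filter_gain(lp$F0, lp), 1)
  expect_equal(filter_gain(lp$F1, lp), 0)
  expect_equal(filter_gain(lp$F0 * 2^1.5, lp), 0.75)
  expect_equal(filter_gain(lp$F0 / 2, lp), 1)    # inside passband
  expect_equal(filter_gain(lp$F1 * 4, lp), 0)    # beyond cutoff
  hp <- filter_params("highpass", 10.67)
  expect_equal(filter_gain(hp$F0, hp), 1)
  expect_equal(filter_gain(hp$F1, hp), 0)
  expect_equal(filter_gain(hp$F0 / 2^1.5, hp), 0.75)
  expect_equal(filter_gain(hp$F0 * 2, hp), 1)
  expect_equal(filter_gain(0, hp), 0) # DC by the raw definition
  # gains stay in [0, 1] across a frequency sweep
  f <- seq(0, 200, by = 0.37)
  for (p in list(lp, hp)) {
    g <- filter_gain(f, p)
    expect_true(all(g >= 0 & g <= 1))
  }
})

test_that("band filtering matches the brute-force bin-loop oracle", {
  set.seed(21)
  img <- matrix(runif(16 * 16, 0, 255), 16, 16)
  for (case in list(list("lowpass", 6), list("highpass", 2),
                    list("lowpass", 14.93))) {
    got <- apply_band_filter(img, filter_params(case[[1]], case[[2]]))
    want <- brute_force_filter(img, case[[1]], case[[2]])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("a lowpass filter above the corner frequency is all-pass", {
  img <- pink64(3)
  out <- apply_band_filter(img, filter_params("lowpass", 8 * 64))
  expect_equal(out, img, tolerance = 1e-8)
})

test_that("a grating above the lowpass cutoff is removed", {
  g <- grating(64, 64, cycles = 16)
  out <- apply_band_filter(g, filter_params("lowpass", 8)) # F1 = 8 < 16
  expect_lt(max(abs(out - mean(g))), 1e-6)
})

test_that("filtered spectra equal input spectra times the gain grid", {
  img <- pink64(7)
  p <- filter_params("lowpass", 14.93)
  out <- apply_band_filter(img, p)
  a_in <- decompose_image(img)$amplitude
  a_out <- decompose_image(out)$amplitude
  grid <- frequency_grid(64, 64)
  gain <- filter_gain(grid$radial_cpi, p)
  gain[1, 1] <- 1
  expect_equal(a_out, a_in * gain, tolerance = 1e-6)
  # energy beyond F1 is gone, energy inside the passband untouched
  expect_lt(sum(a_out[grid$radial_cpi > 14.93]^2), 1e-12 * sum(a_in^2))
  pass <- grid$radial_cpi <= p$F0
  expect_equal(a_out[pass], a_in[pass], tolerance = 1e-10)
})

test_that("lowpass output energy is non-increasing in stricter cutoffs", {
  img <- pink64(11)
  energy <- vapply(c(64, 32, 16, 8, 4), function(F1) {
    out <- apply_band_filter(img, filter_params("lowpass", F1))
    sum((out - mean(out))^2)
  }, numeric(1))
  expect_true(all(diff(energy) <= 1e-8))
})

test_that("phase scrambling preserves the amplitude spectrum at every w", {
  img <- pink64(5)
  a_in <- decompose_image(img)$amplitude
  for (w in c(0, 0.15, 0.4, 0.5, 0.7, 1)) {
    out <- phase_scramble(img, w, seed = 31)
    a_out <- decompose_image(out)$amplitude
    expect_lt(max(abs(a_out - a_in)) / max(a_in), 1e-6)
  }
})

test_that("phase scrambling at w = 0 returns the original image", {
  img <- pink64(6)
  expect_equal(phase_scramble(img, 0, seed = 1), img, tolerance = 1e-8)
})

test_that("phase scrambling is seed-reproducible and seed-sensitive", {
  img <- pink64(8)
  a <- phase_scramble(img, 0.6, seed = 42)
  b <- phase_scramble(img, 0.6, seed = 42)
  c <- phase_scramble(img, 0.6, seed = 43)
  expect_identical(a, b)
  expect_gt(max(abs(a - c)), 1)
  expect_error(phase_scramble(img, 1.2, seed = 1), "\\[0, 1\\]")
  expect_error(phase_scramble(img, -0.1, seed = 1), "\\[0, 1\\]")
})

test_that("full scrambling decorrelates the phase spectrum", {
  img <- pink64(9)
  phi_in <- decompose_image(img)$phase
  align <- vapply(1:10, function(s) {
    phi_out <- decompose_image(phase_scramble(img, 1, seed = s))$phase
    mean(cos(phi_out - phi_in))
  }, numeric(1))
  expect_lt(abs(mean(align)), 0.05)
  # and at w = 0 the phases align perfectly
  phi0 <- decompose_image(phase_scramble(img, 0, seed = 1))$phase
  expect_gt(mean(cos(phi0 - phi_in)), 0.999)
})

test_that("pixel correlation with the original decreases with w", {
  img <- pink64(10)
  ws <- c(0, 0.25, 0.5, 0.75, 1)
  corr <- vapply(ws, function(w) {
    mean(vapply(1:5, function(s)
      stats::cor(as.vector(img), as.vector(phase_scramble(img, w, s))),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(corr) <= 0.02))
  expect_gt(corr[1], 0.999)
  expect_lt(abs(corr[5]), 0.2)
})

test_that("whitening multiplies amplitude by the documented gain", {
  img <- pink64(12)
  out <- whiten(img)
  a_in <- decompose_image(img)$amplitude
  a_out <- decompose_image(out)$amplitude
  grid <- frequency_grid(64, 64)
  fN <- grid$nyquist_cpi
  gain <- ifelse(grid$radial_cpi > 0,
                 (grid$radial_cpi / fN) * exp(1 - (grid$radial_cpi / fN)^4),
                 1)
  expect_equal(a_out, a_in * gain, tolerance = 1e-8)
})

test_that("whitening a constant image preserves it", {
  x <- matrix(93, 16, 16)
  expect_equal(whiten(x), x, tolerance = 1e-8)
})

test_that("whitening flattens a 1/f spectrum", {
  slopes <- vapply(1:5, function(s) {
    spectral_slope(whiten(gen_pink_image(synthetic_image_params(128, 128),
                                         seed = s)))
  }, numeric(1))
  expect_lt(max(abs(slopes)), 0.15)
})

test_that("luminance standardization hits its targets without clipping", {
  g <- grating(64, 64, cycles = 5, amp = 33) + 17
  out <- normalize_mean_sd(g)
  expect_equal(mean(out), 128, tolerance = 1e-6)
  expect_equal(stats::sd(out), 72.11, tolerance = 1e-6)
  expect_equal(normalize_mean_sd(out), out, tolerance = 1e-9) # idempotent
  expect_error(normalize_mean_sd(matrix(5, 8, 8)), "constant")
})

test_that("range stretching spans exactly 0-255", {
  img <- pink64(13) * 0.3 + 70
  out <- stretch_full_range(img)
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  expect_equal(stretch_full_range(out), out, tolerance = 1e-9)
  expect_equal(stretch_full_range(matrix(c(10, 20, 10, 20), 2, 2)),
               matrix(c(0, 255, 0, 255), 2, 2))
  expect_error(stretch_full_range(matrix(1, 4, 4)), "constant")
})

test_that("packaged level grids match the published parameter sets", {
  hum <- degradation_presets("human")
  cnn <- degradation_presets("cnn")
  expect_equal(hum$highpass, c(120.68, 85.33, 60.34, 10.67))
  expect_equal(hum$lowpass, c(5.66, 9.19, 14.93, 64))
  expect_equal(hum$phase_scramble, c(0.70, 0.65, 0.60, 0.40))
  expect_length(cnn$lowpass, 15)
  expect_length(cnn$highpass, 15)
  expect_length(cnn$phase_scramble, 15)
  # the four human levels are embedded in each fifteen-level grid
  for (k in names(hum)) expect_true(all(hum[[k]] %in% cnn[[k]]))
})

test_that("stimulus-set manifests enumerate and reproduce exactly", {
  m1 <- build_stimulus_set(paste0("img", 1:4), c("lowpass", "phase_scramble"),
                           degradation_presets("human"), seed = 5)
  expect_equal(nrow(m1), 4 * 2 * 4)
  m2 <- build_stimulus_set(paste0("img", 1:4), c("lowpass", "phase_scramble"),
                           degradation_presets("human"), seed = 5)
  expect_identical(m1, m2)
  m3 <- build_stimulus_set("solo", "lowpass", list(lowpass = 14.93),
                           seed = 1)
  expect_equal(nrow(m3), 1)
  expect_error(build_stimulus_set(list(), "lowpass",
                                  list(lowpass = 14.93), 1), "empty")
})

test_that("written stimuli are pixel-identical across reruns", {
  imgs <- list(a = pink64(14), b = pink64(15))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  lv <- list(phase_scramble = c(0.4, 0.7))
  m1 <- build_stimulus_set(imgs, "phase_scramble", lv, seed = 99,
                           out_dir = d1)
  m2 <- build_stimulus_set(imgs, "phase_scramble", lv, seed = 99,
                           out_dir = d2)
  expect_equal(nrow(m1), 4)
  for (i in seq_len(nrow(m1))) {
    expect_identical(readBin(m1$path[i], "raw", 1e6),
                     readBin(m2$path[i], "raw", 1e6))
  }
})

test_that("RGB images share one scramble field across channels", {
  rgb <- array(0, c(32, 32, 3))
  base <- gen_pink_image(synthetic_image_params(32, 32), 1)
  for (ch in 1:3) rgb[, , ch] <- base
  out <- phase_scramble(rgb, 0.8, seed = 4)
  # identical channels in, identical channels out (same noise field)
  expect_equal(out[, , 1], out[, , 2], tolerance = 1e-10)
  expect_equal(out[, , 2], out[, , 3], tolerance = 1e-10)
})
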