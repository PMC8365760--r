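# Shared fixtures, built in code at test time.

pink64 <- function(seed = 1, class_signal = 1) {
  gen_pink_image(synthetic_image_params(64, 64), seed = seed)
}

# horizontal cosine grating with `cycles` periods across the width,
# mean 128, non-constant, guaranteed non-clipping under mean/SD
# standardization (a sine deviates at most sqrt(2) SDs from its mean)
grating <- function(h = 64, w = 64, cycles = 8, amp = 40) {
  x <- matrix(0:(w - 1), h, w, byrow = TRUE)
  128 + amp * cos(2 * pi * cycles * x / w)
}

# independent bin-loop filter oracle: scalar gain per bin, parabola in
# octaves written out inline (kept independent of filter_gain())
brute_force_filter <- function(img, kind, F1) {
  h <- nrow(img); w <- ncol(img)
  F0 <- if (kind == "lowpass") F1 / 8 else F1 * 8
  F <- stats::fft(img)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      v <- i - 1; if (v > h / 2) v <- v - h
      u <- j - 1; if (u > w / 2) u <- u - w
      f <- h * sqrt((u / w)^2 + (v / h)^2)
      g <- if (f == 0) 1
      else if (kind == "lowpass") {
        x <- log2(f / F0)
        if (x <= 0) 1 else if (x >= 3) 0 else 1 - (x / 3)^2
      } else {
        x <- log2(F0 / f)
        if (x <= 0) 1 else if (x >= 3) 0 else 1 - (x / 3)^2
      }
      F[i, j] <- F[i, j] * g
    }
  }
  Re(stats::fft(F, inverse = TRUE) / (h * w))
}

# bisection threshold oracle, independent of the closed form
bisect_threshold <- function(alpha, beta, gamma, lambda, criterion,
                             tol = 1e-12) {
  lo <- 1e-9; hi <- alpha
  while (weibull_psy(hi, alpha, beta, gamma, lambda) < criterion) hi <- hi * 2
  while (hi - lo > tol * hi) {
    mid <- (lo + hi) / 2
    if (weibull_psy(mid, alpha, beta, gamma, lambda) < criterion) lo <- mid
    else hi <- mid
  }
  (lo + hi) / 2
}

# simple recovery design along the rising part of a Weibull with the
# given scale
recovery_design <- function(alpha, kind = "lowpass", n_trials = 2000) {
  clar <- alpha * 2^seq(-2, 1.5, by = 0.5)
  data.frame(kind = kind, level = clarity_inverse(kind, clar),
             n_trials = n_trials)
}
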