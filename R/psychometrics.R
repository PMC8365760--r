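# Weibull psychometric fitting: maximum likelihood over (alpha, beta,
# lambda) with the guess rate fixed at 0.5 (two-choice task), the 80%
# threshold in original stimulus units, and a parametric bootstrap for
# its 95% confidence interval.

#' Weibull psychometric function
#'
#' \deqn{\psi(x) = \gamma + (1 - \gamma - \lambda)
#'   \left(1 - e^{-(x/\alpha)^\beta}\right)}
#' where `x` is the stimulus clarity (> 0), `alpha` the scale, `beta`
#' the shape, `gamma` the guess rate (lower asymptote) and `lambda`
#' the lapse rate (upper-asymptote shortfall).
#'
#' @param x clarity value(s), > 0.
#' @param alpha,beta positive scale and shape.
#' @param gamma guess rate (default 0.5, two-alternative task).
#' @param lambda lapse rate, with `gamma + lambda < 1`.
#' @return probability of a correct response.
#' @examples
#' weibull_psy(6.02, alpha = 6.02, beta = 3) # 0.5 + 0.5*(1 - exp(-1))
#' @export
weibull_psy <- function(x, alpha, beta, gamma = 0.5, lambda = 0) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (gamma < 0 || lambda < 0 || gamma + lambda >= 1)
    stop("require 0 <= gamma, 0 <= lambda, gamma + lambda < 1")
  if (any(x < 0)) stop("clarity values must be non-negative")
  gamma + (1 - gamma - lambda) * (1 - exp(-(x / alpha)^beta))
}

#' Map a degradation level onto the clarity axis
#'
#' Each degradation kind is oriented so that accuracy increases with
#' clarity: lowpass clarity is the F1 cutoff itself (higher cutoff =
#' more detail), highpass clarity is `1/F1` (a lower cutoff passes
#' more of the spectrum), and phase-scramble clarity is `1 - w` (the
#' proportion of original phase retained).
#'
#' @param kind `"lowpass"`, `"highpass"` or `"phase_scramble"`.
#' @param level degradation level in original units (F1 cpi or w).
#' @return clarity value(s), > 0 for valid levels.
#' @seealso [clarity_inverse()]
#' @export
clarity_axis <- function(kind, level) {
  switch(kind,
    lowpass = level,
    highpass = 1 / level,
    phase_scramble = 1 - level,
    stop("unknown degradation kind: ", kind)
  )
}

#' Invert the clarity mapping back to original units
#'
#' @param kind degradation kind (see [clarity_axis()]).
#' @param clarity clarity value(s).
#' @return degradation level in original units.
#' @export
clarity_inverse <- function(kind, clarity) {
  switch(kind,
    lowpass = clarity,
    highpass = 1 / clarity,
    phase_scramble = 1 - clarity,
    stop("unknown degradation kind: ", kind)
  )
}

#' @keywords internal
#' @noRd
weibull_nll <- function(par, clarity, k, n, gamma) {
  alpha <- exp(par[1]); beta <- exp(par[2]); lambda <- par[3]
  p <- gamma + (1 - gamma - lambda) * (1 - exp(-(clarity / alpha)^beta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

#' @keywords internal
#' @noRd
fit_weibull_counts <- function(clarity, k, n, gamma = 0.5,
                               lambda_max = 0.05, starts = NULL) {
  lo_a <- log(min(clarity)) - log(100)
  hi_a <- log(max(clarity)) + log(100)
  lower <- c(lo_a, log(0.05), 0)
  upper <- c(hi_a, log(50), lambda_max)
  if (is.null(starts)) {
    qa <- stats::quantile(clarity, c(0.2, 0.4, 0.6, 0.8))
    starts <- expand.grid(a = log(qa), b = log(c(0.5, 1.5, 3, 8)),
                          l = 0.01)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- pmin(pmax(as.numeric(starts[i, ]), lower), upper)
    res <- tryCatch(
      stats::optim(par0, weibull_nll, clarity = clarity, k = k, n = n,
                   gamma = gamma, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best)) return(NULL)
  hit_bound <- best$par[1] <= lo_a + 1e-6 || best$par[1] >= hi_a - 1e-6 ||
    best$par[2] >= log(50) - 1e-6
  list(alpha = exp(best$par[1]), beta = exp(best$par[2]),
       lambda = min(max(best$par[3], 0), lambda_max), nll = best$value,
       converged = best$convergence == 0 && !hit_bound)
}

#' Fit a Weibull psychometric function to trial data
#'
#' Maximizes the Bernoulli log-likelihood over `(alpha, beta, lambda)`
#' with the guess rate fixed at 0.5 and the lapse rate constrained to
#' `[0, 0.05]`, from a multistart grid of initial values. Degenerate
#' data (all correct everywhere, or at chance everywhere) push the
#' scale to a box bound; such fits are returned with
#' `converged = FALSE` and a threshold outside the tested range rather
#' than as an error.
#'
#' @param trials data.frame with columns `level` and `correct`
#'   (logical/0-1), one row per trial, all from one observer and one
#'   degradation kind; alternatively pre-aggregated columns `level`,
#'   `k`, `n`.
#' @param kind degradation kind, used to orient the clarity axis.
#' @param lambda_max upper bound on the lapse rate (default 0.05).
#' @return an object of class `psyfit`: list with `alpha`, `beta`,
#'   `gamma`, `lambda` (clarity-axis parameters), `threshold80` (in
#'   original units), `ci95` (NA until [bootstrap_ci()] is run),
#'   `converged`, `kind`, `criterion`, and the per-level data used.
#' @examples
#' d <- data.frame(level = rep(c(2, 4, 6, 8, 12), each = 50),
#'                 correct = rbinom(250, 1, 0.9))
#' fit <- fit_psychometric(d, kind = "lowpass")
#' @export
fit_psychometric <- function(trials, kind, lambda_max = 0.05) {
  if (!all(c("level") %in% names(trials)))
    stop("trials must contain a 'level' column")
  if (all(c("k", "n") %in% names(trials))) {
    agg <- trials[, c("level", "k", "n")]
  } else {
    if (!"correct" %in% names(trials))
      stop("trials must contain 'correct' or pre-aggregated 'k'/'n'")
    agg <- stats::aggregate(cbind(k = as.numeric(trials$correct),
                                  n = rep(1, nrow(trials))) ~ level,
                            data = trials, FUN = sum)
  }
  agg <- agg[order(agg$level), ]
  if (nrow(agg) < 3) stop("need trials at >= 3 distinct levels")
  clarity <- clarity_axis(kind, agg$level)
  if (any(clarity <= 0))
    stop("levels map to non-positive clarity; check 'kind' and levels")
  res <- fit_weibull_counts(clarity, agg$k, agg$n, lambda_max = lambda_max)
  if (is.null(res)) stop("optimization failed from every start")
  fit <- structure(
    list(alpha = res$alpha, beta = res$beta, gamma = 0.5,
         lambda = res$lambda, kind = kind, criterion = 0.80,
         threshold80 = NA_real_, ci95 = c(NA_real_, NA_real_),
         n_boot = 0L, converged = res$converged, logLik = -res$nll,
         data = data.frame(level = agg$level, clarity = clarity,
                           k = agg$k, n = agg$n)),
    class = "psyfit")
  fit$threshold80 <- threshold_at(fit, 0.80)
  fit
}

#' Stimulus level at a criterion accuracy
#'
#' Solves the fitted Weibull analytically for the clarity at which
#' predicted accuracy equals `criterion`, then maps back to original
#' stimulus units through the clarity-axis inverse.
#'
#' @param fit a `psyfit` object, or a list with `alpha`, `beta`,
#'   `gamma`, `lambda` and `kind`.
#' @param criterion target accuracy, strictly between `gamma` and
#'   `1 - lambda`.
#' @return threshold level in original units.
#' @export
threshold_at <- function(fit, criterion = 0.80) {
  g <- fit$gamma; l <- fit$lambda
  if (criterion <= g || criterion >= 1 - l)
    stop("criterion must lie strictly between gamma and 1 - lambda")
  q <- (criterion - g) / (1 - g - l)
  x <- fit$alpha * (-log(1 - q))^(1 / fit$beta)
  clarity_inverse(fit$kind, x)
}

#' Parametric bootstrap CI for the threshold
#'
#' Wichmann-Hill style parametric bootstrap: for each replicate, the
#' correct counts at every tested level are redrawn as binomials with
#' success probability given by the fitted curve and the original
#' per-level trial counts; the curve is refitted (started from the
#' point estimate) and the threshold recorded. The interval is the
#' 2.5th-97.5th percentile range, mapped to original units. Replicates
#' that fail to converge are dropped and counted; if more than 10%
#' fail, the interval is flagged.
#'
#' @param fit a converged `psyfit` object.
#' @param n_boot number of bootstrap replicates (default 2000).
#' @param seed integer seed; the same seed reproduces the interval.
#' @param level confidence level (default 0.95).
#' @return the `psyfit` object with `ci95`, `n_boot`, `boot_failures`
#'   and `ci_flagged` filled in.
#' @export
bootstrap_ci <- function(fit, n_boot = 2000, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "psyfit"))
  if (!fit$converged) stop("bootstrap requires a converged fit")
  dat <- fit$data
  p_hat <- weibull_psy(dat$clarity, fit$alpha, fit$beta, fit$gamma,
                       fit$lambda)
  start <- matrix(c(log(fit$alpha), log(fit$beta), fit$lambda), nrow = 1)
  q <- (fit$criterion - fit$gamma) / (1 - fit$gamma - fit$lambda)
  thr <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      kb <- stats::rbinom(length(p_hat), dat$n, p_hat)
      r <- fit_weibull_counts(dat$clarity, kb, dat$n,
                              starts = as.data.frame(start))
      if (is.null(r) || !r$converged) return(NA_real_)
      qb <- (fit$criterion - fit$gamma) / (1 - fit$gamma - r$lambda)
      r$alpha * (-log(1 - qb))^(1 / r$beta)
    }, numeric(1))
  })
  fails <- sum(is.na(thr))
  ci_clarity <- stats::quantile(thr, c((1 - level) / 2, 1 - (1 - level) / 2),
                                na.rm = TRUE, names = FALSE)
  ci <- sort(clarity_inverse(fit$kind, ci_clarity))
  fit$ci95 <- ci
  fit$n_boot <- as.integer(n_boot)
  fit$boot_failures <- fails
  fit$ci_flagged <- fails > 0.1 * n_boot
  fit
}

#' @export
print.psyfit <- function(x, ...) {
  cat(sprintf("Weibull psychometric fit (%s)\n", x$kind))
  cat(sprintf("  alpha %.4g  beta %.4g  gamma %.2f  lambda %.4g  (%s)\n",
              x$alpha, x$beta, x$gamma, x$lambda,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  threshold (%.0f%% accuracy): %.4g", 100 * x$criterion,
              x$threshold80))
  if (!any(is.na(x$ci95)))
    cat(sprintf("  [%.4g, %.4g] (%d bootstrap replicates)",
                x$ci95[1], x$ci95[2], x$n_boot))
  cat("\n")
  invisible(x)
}
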