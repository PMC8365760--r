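# Comparison statistics between two classifiers (e.g. an artificial
# classifier and pooled human observers): accuracy ratio and
# image-level agreement ratio, with Katz log-method confidence
# intervals, normal-deviate p-values and Bonferroni correction.

#' Correct/total count pair for two classifiers
#'
#' @param k_c,n_c correct and total trial counts for the artificial
#'   classifier.
#' @param k_h,n_h correct and total trial counts for the human
#'   observers.
#' @return an object of class `CountPair` (list with `k_c`, `n_c`,
#'   `w_c`, `k_h`, `n_h`, `w_h`).
#' @export
count_pair <- function(k_c, n_c, k_h, n_h) {
  if (n_c <= 0 || n_h <= 0) stop("total trial counts must be positive")
  if (k_c < 0 || k_c > n_c || k_h < 0 || k_h > n_h)
    stop("correct counts must lie in [0, n]")
  structure(list(k_c = k_c, n_c = n_c, w_c = n_c - k_c,
                 k_h = k_h, n_h = n_h, w_h = n_h - k_h),
            class = "CountPair")
}

#' @keywords internal
#' @noRd
katz_inference <- function(ratio, se_log, m_comparisons) {
  z <- if (se_log == 0) {
    if (log(ratio) == 0) 0 else sign(log(ratio)) * Inf
  } else log(ratio) / se_log
  ci <- ratio * exp(c(-1, 1) * stats::qnorm(0.975) * se_log)
  p <- 2 * stats::pnorm(-abs(z))
  list(ci95 = ci, z = z, p_raw = p,
       p_corrected = min(1, m_comparisons * p),
       m_comparisons = m_comparisons)
}

#' Accuracy ratio between two classifiers (Katz log method)
#'
#' The ratio of the two accuracies,
#' \deqn{R = \frac{k_c/n_c}{k_h/n_h},}
#' with the standard error of its logarithm from the Katz log method,
#' \deqn{SE(\ln R) = \sqrt{1/k_c - 1/n_c + 1/k_h - 1/n_h},}
#' a 95% interval `exp(ln R +/- 1.96 SE)` and a two-sided p-value from
#' the normal deviate `ln(R)/SE`. Values above 1 mean the artificial
#' classifier is more accurate. If either correct count is zero, the
#' Haldane-Anscombe continuity correction (+0.5 to all four counts) is
#' applied before the log method.
#'
#' @param pair a [count_pair()].
#' @param m_comparisons Bonferroni correction factor for
#'   `p_corrected` (default 4, one per matched degradation level).
#' @return an object of class `ratio_test`: list with `ratio`, `ci95`,
#'   `se_log`, `z`, `p_raw`, `p_corrected`, `m_comparisons`.
#' @examples
#' accuracy_ratio(count_pair(90, 100, 60, 100))$ratio # 1.5
#' @export
accuracy_ratio <- function(pair, m_comparisons = 4) {
  stopifnot(inherits(pair, "CountPair"))
  k_c <- pair$k_c; n_c <- pair$n_c; k_h <- pair$k_h; n_h <- pair$n_h
  if (k_c == 0 || k_h == 0 || k_c == n_c || k_h == n_h) {
    # Haldane-Anscombe: a zero cell (no correct or no wrong responses)
    # breaks the log method; add 0.5 to all four counts
    k_c <- k_c + 0.5; n_c <- n_c + 1
    k_h <- k_h + 0.5; n_h <- n_h + 1
  }
  ratio <- (k_c / n_c) / (k_h / n_h)
  se <- sqrt(1 / k_c - 1 / n_c + 1 / k_h - 1 / n_h)
  inf <- katz_inference(ratio, se, m_comparisons)
  structure(c(list(ratio = ratio, se_log = se), inf), class = "ratio_test")
}

#' Expected image-level agreement between two classifiers
#'
#' The chance rate of image-level agreement implied by the two
#' accuracies alone: the product of the two correct-response rates
#' plus the product of the two error rates,
#' \deqn{E = \frac{k_c}{n_c}\frac{k_h}{n_h} +
#'           \frac{w_c}{n_c}\frac{w_h}{n_h}.}
#' It equals 0.5 whenever either classifier is at chance, and tends to
#' 1 when both approach perfect accuracy.
#'
#' @param pair a [count_pair()].
#' @return expected agreement proportion.
#' @examples
#' expected_agreement(count_pair(90, 100, 80, 100)) # 0.74
#' @export
expected_agreement <- function(pair) {
  stopifnot(inherits(pair, "CountPair"))
  with(pair, (k_c / n_c) * (k_h / n_h) + (w_c / n_c) * (w_h / n_h))
}

#' Observed image-level agreement
#'
#' Fraction of stimuli on which the two classifiers made the same
#' category decision, aligned by stimulus id.
#'
#' @param decisions_h,decisions_c vectors of category labels, one per
#'   stimulus, in the same stimulus order.
#' @param ids_h,ids_c optional stimulus ids used to verify alignment.
#' @return list with `proportion`, `matches`, `n`.
#' @export
observed_agreement <- function(decisions_h, decisions_c,
                               ids_h = NULL, ids_c = NULL) {
  if (length(decisions_h) != length(decisions_c))
    stop("decision vectors differ in length")
  if (!is.null(ids_h) || !is.null(ids_c)) {
    if (is.null(ids_h) || is.null(ids_c) || !identical(ids_h, ids_c))
      stop("stimulus ids are misaligned between the two classifiers")
  }
  m <- sum(decisions_h == decisions_c)
  list(proportion = m / length(decisions_h), matches = m,
       n = length(decisions_h))
}

#' Agreement ratio with log-method inference
#'
#' The ratio of observed to expected image-level agreement. Values
#' near 1 indicate chance agreement given the two accuracies; above 1,
#' systematic agreement (shared successes and failures on the same
#' images); below 1, systematic disagreement. Inference mirrors the
#' accuracy-ratio machinery: the observed agreement is treated as a
#' binomial proportion over `n_images`, the expected agreement's
#' variance is propagated from the two accuracy proportions by the
#' delta method, and the two log-variances are summed.
#'
#' @param observed_matches number of stimuli with identical decisions.
#' @param n_images number of aligned stimuli.
#' @param pair the [count_pair()] from which expected agreement is
#'   derived.
#' @param m_comparisons Bonferroni factor (default 4).
#' @return an object of class `agreement_test`: list with `observed`,
#'   `expected`, `ratio`, `ci95`, `p_raw`, `p_corrected`,
#'   `m_comparisons`.
#' @export
agreement_ratio <- function(observed_matches, n_images, pair,
                            m_comparisons = 4) {
  stopifnot(inherits(pair, "CountPair"))
  if (n_images <= 0) stop("n_images must be positive")
  expected <- expected_agreement(pair)
  if (expected <= 0) stop("expected agreement is zero; ratio undefined")
  # continuity: the log method needs an observed proportion strictly
  # inside (0, 1); the clamped count feeds the inference only, the
  # reported ratio keeps the raw observed proportion
  k_o <- min(max(observed_matches, 0.5), n_images - 0.5)
  obs <- observed_matches / n_images
  ratio <- obs / expected
  p_c <- pair$k_c / pair$n_c
  p_h <- pair$k_h / pair$n_h
  # delta method: E = p_c p_h + (1-p_c)(1-p_h),
  # dE/dp_c = 2 p_h - 1, dE/dp_h = 2 p_c - 1
  var_e <- (2 * p_h - 1)^2 * p_c * (1 - p_c) / pair$n_c +
    (2 * p_c - 1)^2 * p_h * (1 - p_h) / pair$n_h
  var_log <- (1 / k_o - 1 / n_images) + var_e / expected^2
  se <- sqrt(max(var_log, 0))
  inf <- katz_inference((k_o / n_images) / expected, se, m_comparisons)
  structure(c(list(observed = obs, expected = expected, ratio = ratio,
                   se_log = se), inf),
            class = c("agreement_test", "ratio_test"))
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of comparisons and caps at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param m number of comparisons (default 4, the matched degradation
#'   levels per type).
#' @return corrected p-values.
#' @export
bonferroni <- function(p_values, m = 4) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, m * p_values)
}

#' Aggregate per-run classifier scores into decisions and accuracies
#'
#' Each run's score in `[0, 1]` is rounded to the nearest integer (0.5
#' rounds up) to give a binary decision per stimulus and run. The
#' group accuracy is the mean of the per-run accuracies, and the group
#' image-level decision is the majority vote across runs, with ties
#' broken by rounding the mean score.
#'
#' @param scores numeric matrix, stimuli x runs, values in `[0, 1]`.
#' @param true_labels 0/1 vector, one per stimulus.
#' @return list with `decisions` (stimuli x runs 0/1 matrix),
#'   `run_accuracy` (per run), `group_accuracy`, `group_decision`
#'   (majority vote per stimulus).
#' @export
aggregate_predictions <- function(scores, true_labels) {
  scores <- as.matrix(scores)
  if (ncol(scores) == 0 || nrow(scores) == 0) stop("empty score grid")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  if (length(true_labels) != nrow(scores))
    stop("one true label per stimulus is required")
  dec <- floor(scores + 0.5) # round half up
  run_acc <- colMeans(dec == true_labels)
  frac <- rowMeans(dec)
  group_dec <- ifelse(frac > 0.5, 1L, ifelse(frac < 0.5, 0L,
                                             floor(rowMeans(scores) + 0.5)))
  list(decisions = dec, run_accuracy = run_acc,
       group_accuracy = mean(run_acc), group_decision = as.integer(group_dec))
}

#' @export
print.ratio_test <- function(x, ...) {
  lab <- if (inherits(x, "agreement_test")) "Agreement ratio" else
    "Accuracy ratio"
  cat(sprintf("%s: %.4g  95%% CI [%.4g, %.4g]\n", lab, x$ratio,
              x$ci95[1], x$ci95[2]))
  cat(sprintf("  p = %.4g (raw), %.4g (Bonferroni, m = %d)\n",
              x$p_raw, x$p_corrected, x$m_comparisons))
  invisible(x)
}
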