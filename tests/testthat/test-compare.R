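test_that("accuracy ratio arithmetic and validation", {
  expect_equal(accuracy_ratio(count_pair(80, 100, 80, 100))$ratio, 1)
  expect_equal(accuracy_ratio(count_pair(90, 100, 60, 100))$ratio, 1.5)
  expect_error(count_pair(5, 0, 5, 10), "positive")
  expect_error(count_pair(11, 10, 5, 10), "\\[0, n\\]")
  r <- accuracy_ratio(count_pair(90, 100, 60, 100))
  expect_lte(r$ci95[1], r$ratio)
  expect_gte(r$ci95[2], r$ratio)
})

test_that("Katz interval and p-value match a binomial bootstrap oracle", {
  pair <- count_pair(45, 60, 50, 60)
  r <- accuracy_ratio(pair)
  set.seed(1234)
  n_rep <- 1e5
  boot <- (stats::rbinom(n_rep, 60, 45 / 60) / 60) /
    (stats::rbinom(n_rep, 60, 50 / 60) / 60)
  ci_boot <- unname(stats::quantile(boot, c(0.025, 0.975)))
  # Monte-Carlo and asymptotic intervals agree to a few percent
  expect_lt(abs(r$ci95[1] - ci_boot[1]), 0.05)
  expect_lt(abs(r$ci95[2] - ci_boot[2]), 0.05)
  # p-value consistent with the bootstrap tail mass at the null ratio
  p_boot <- 2 * min(mean(boot <= 1), mean(boot >= 1))
  expect_lt(abs(r$p_raw - p_boot), 0.1)
})

test_that("accuracy-ratio intervals shrink as counts grow", {
  widths <- vapply(c(1e2, 1e3, 1e4), function(n) {
    r <- accuracy_ratio(count_pair(round(0.8 * n), n, round(0.7 * n), n))
    r$ci95[2] - r$ci95[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("zero cells get the continuity correction instead of breaking", {
  r0 <- accuracy_ratio(count_pair(0, 50, 40, 50))
  expect_true(is.finite(r0$ratio) && is.finite(r0$se_log))
  r1 <- accuracy_ratio(count_pair(50, 50, 50, 50))
  expect_equal(r1$ratio, 1)
  expect_equal(r1$p_raw, 1)
})

test_that("expected agreement follows the accuracy products", {
  expect_equal(expected_agreement(count_pair(100, 100, 100, 100)), 1)
  expect_equal(expected_agreement(count_pair(50, 100, 50, 100)), 0.5)
  expect_equal(expected_agreement(count_pair(90, 100, 80, 100)), 0.74)
  # symmetric in the two systems
  expect_equal(expected_agreement(count_pair(35, 50, 90, 120)),
               expected_agreement(count_pair(90, 120, 35, 50)))
  # chance performance by either system pins expectation at 0.5
  for (k in c(10, 60, 110)) {
    expect_equal(expected_agreement(count_pair(60, 120, k, 120)), 0.5)
  }
})

test_that("observed agreement counts image-level matches", {
  a <- c("animal", "vehicle", "animal", "animal")
  expect_equal(observed_agreement(a, a)$proportion, 1)
  b <- ifelse(a == "animal", "vehicle", "animal")
  expect_equal(observed_agreement(a, b)$proportion, 0)
  h <- rep(c("animal", "vehicle"), 5)
  c2 <- c(h[1:5], ifelse(h[6:10] == "animal", "vehicle", "animal"))
  expect_equal(observed_agreement(h, c2)$proportion, 0.5)
  expect_error(observed_agreement(a, a[1:3]), "length")
  expect_error(observed_agreement(a, a, ids_h = c("s1", "s2", "s3", "s4"),
                                  ids_c = c("s1", "s2", "s4", "s3")),
               "misaligned")
})

test_that("agreement ratio closed forms", {
  pair <- count_pair(75, 100, 75, 100)
  ag <- agreement_ratio(100, 100, pair)
  expect_equal(ag$observed, 1)
  expect_equal(ag$expected, 0.625)
  expect_equal(ag$ratio, 1.6)
  ag2 <- agreement_ratio(62.5, 100, pair)
  expect_equal(ag2$ratio, 1)
})

test_that("agreement ratio tends to 1 for near-ceiling observers", {
  m <- observer_model(alpha = 0.1, beta = 3, lambda = 0, kinds = "lowpass")
  design <- data.frame(kind = "lowpass", level = 10, n_trials = 2000)
  pp <- simulate_paired_observers(m, m, design, 0, seed = 3)
  pair <- count_pair(sum(pp$c$correct), 2000, sum(pp$h$correct), 2000)
  oa <- observed_agreement(pp$h$decision, pp$c$decision)
  ag <- agreement_ratio(oa$matches, 2000, pair)
  expect_lt(abs(ag$ratio - 1), 0.02)
})

test_that("independent observers give chance-level agreement ratios", {
  m <- observer_model(alpha = 1, beta = 3, lambda = 0.01, kinds = "lowpass")
  design <- data.frame(kind = "lowpass", level = 1.2, n_trials = 2000)
  covered <- vapply(1:50, function(s) {
    pp <- simulate_paired_observers(m, m, design, 0, seed = s)
    pair <- count_pair(sum(pp$c$correct), 2000, sum(pp$h$correct), 2000)
    oa <- observed_agreement(pp$h$decision, pp$c$decision)
    ag <- agreement_ratio(oa$matches, 2000, pair)
    ag$ci95[1] <= 1 && 1 <= ag$ci95[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("shared image difficulty produces systematic agreement", {
  m <- observer_model(alpha = 1, beta = 3, lambda = 0.01, kinds = "lowpass")
  design <- data.frame(kind = "lowpass", level = 1.2, n_trials = 2000)
  pp <- simulate_paired_observers(m, m, design, shared_difficulty_sd = 1,
                                  seed = 11)
  pair <- count_pair(sum(pp$c$correct), 2000, sum(pp$h$correct), 2000)
  oa <- observed_agreement(pp$h$decision, pp$c$decision)
  ag <- agreement_ratio(oa$matches, 2000, pair)
  expect_gt(ag$ci95[1], 1)
  expect_lt(ag$p_corrected, 0.05)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.01), 0.04)
  expect_equal(bonferroni(0.5), 1)
  expect_equal(bonferroni(0), 0)
  expect_equal(bonferroni(c(0.01, 0.3), m = 2), c(0.02, 0.6))
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

test_that("prediction aggregation rounds, averages and votes", {
  scores <- matrix(0.6, nrow = 4, ncol = 3)
  labels <- c(1, 1, 1, 1)
  agg <- aggregate_predictions(scores, labels)
  expect_true(all(agg$decisions == 1))
  expect_equal(agg$group_accuracy, 1)
  # 0.5 rounds up
  expect_equal(aggregate_predictions(matrix(0.5, 1, 1), 1)$decisions[1, 1], 1)
  # mean of per-run accuracies
  sc <- cbind(rep(c(0.9, 0.1), 5), rep(c(0.9, 0.1), each = 5))
  lab <- rep(c(1, 0), 5)
  agg2 <- aggregate_predictions(sc, lab)
  expect_equal(agg2$run_accuracy[1], 1)
  expect_equal(agg2$group_accuracy, mean(agg2$run_accuracy))
  # tie across runs falls back to the rounded mean score
  sc3 <- matrix(c(0.9, 0.08), 1, 2) # decisions 1 and 0, mean score 0.49
  expect_equal(aggregate_predictions(sc3, 1)$group_decision, 0L)
  expect_error(aggregate_predictions(matrix(1.2, 1, 1), 1), "\\[0, 1\\]")
  expect_error(aggregate_predictions(matrix(numeric(0), 0, 0), numeric(0)),
               "empty")
})

test_that("the accuracy-ratio test holds its type-I error rate", {
  set.seed(2024)
  rej <- vapply(1:1000, function(i) {
    k1 <- stats::rbinom(1, 500, 0.75)
    k2 <- stats::rbinom(1, 500, 0.75)
    accuracy_ratio(count_pair(k1, 500, k2, 500),
                   m_comparisons = 1)$p_raw < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})
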