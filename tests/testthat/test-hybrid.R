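mk_pred <- function(p, y) {
  data.frame(video_id = sprintf("v%03d", seq_along(p)), true_group = y,
             p_gts = p, fold_id = rep("F", length(p)),
             stringsAsFactors = FALSE)
}

test_that("confidence stratification uses a strict threshold in both tails", {
  pr <- mk_pred(c(0.95, 0.05, 0.5), c("GTS", "HC", "GTS"))
  s <- stratify_by_confidence(pr, 0.9)
  expect_setequal(s$high$p_gts, c(0.95, 0.05))
  expect_equal(s$low$p_gts, 0.5)
  # exactly at the threshold counts as low-confidence
  s2 <- stratify_by_confidence(mk_pred(c(0.9, 0.1), c("GTS", "HC")), 0.9)
  expect_equal(nrow(s2$high), 0)
  expect_equal(nrow(s2$low), 2)
  expect_error(stratify_by_confidence(pr, 0.4), "confidence_threshold")
  expect_error(stratify_by_confidence(pr, 1), "confidence_threshold")
})

test_that("stratification partitions uniform probabilities at the expected rate", {
  set.seed(19)
  pr <- mk_pred(runif(1000), sample(c("GTS", "HC"), 1000, replace = TRUE))
  s <- stratify_by_confidence(pr, 0.9)
  expect_equal(nrow(s$high) + nrow(s$low), 1000)
  expect_length(intersect(s$high$video_id, s$low$video_id), 0)
  # P(p > 0.9 or p < 0.1) = 0.2 under the uniform
  expect_lt(abs(nrow(s$high) / 1000 - 0.2), 3 * sqrt(0.2 * 0.8 / 1000))
})

test_that("subgroup accuracy is the plain fraction correct", {
  expect_equal(subgroup_accuracy(mk_pred(c(0.9, 0.2), c("GTS", "HC"))), 100)
  expect_equal(subgroup_accuracy(mk_pred(0.9, "HC")), 0)
  # 140 of 143 correct reproduces the printed-precision regime
  p <- c(rep(0.95, 140), rep(0.05, 3))
  y <- rep("GTS", 143)
  expect_equal(round(subgroup_accuracy(mk_pred(p, y)), 1), 97.9)
  expect_error(subgroup_accuracy(mk_pred(numeric(0), character(0))), "empty")
})

test_that("review burden reproduces the printed percentages", {
  expect_equal(round(review_burden(71, 214), 1), 33.2)
  expect_equal(round(review_burden(54, 214), 1), 25.2)
  expect_equal(review_burden(0, 214), 0)
  expect_error(review_burden(5, 0), "n_total")
  expect_error(review_burden(-1, 10), "n_low")
})

test_that("analytic combined accuracy is the weighted subgroup mean", {
  expect_equal(round(combined_accuracy(143, 97.9, 71, 95), 2), 96.94)
  expect_equal(round(combined_accuracy(160, 95.6, 54, 95), 2), 95.45)
  expect_equal(combined_accuracy(10, 88, 0, 42), 88)  # degenerate subgroup
  expect_error(combined_accuracy(0, 50, 0, 50), "not both zero")
  expect_error(combined_accuracy(10, 150, 5, 90), "percentages")
})

test_that("combined accuracy is monotone in subgroup and expert accuracy", {
  grid <- seq(0, 100, by = 10)
  ca_high <- vapply(grid, function(a) combined_accuracy(60, a, 40, 80), numeric(1))
  ca_exp <- vapply(grid, function(e) combined_accuracy(60, 80, 40, e), numeric(1))
  expect_true(all(diff(ca_high) >= 0))
  expect_true(all(diff(ca_exp) >= 0))
})

test_that("raising the confidence threshold never shrinks the review set", {
  set.seed(4)
  pr <- mk_pred(runif(300), sample(c("GTS", "HC"), 300, replace = TRUE))
  n_low <- vapply(seq(0.5, 0.95, by = 0.05),
                  function(t) nrow(stratify_by_confidence(pr, t)$low), numeric(1))
  expect_true(all(diff(n_low) >= 0))
})

test_that("run_hybrid combines automated and expert decisions coherently", {
  # perfect expert + all high-confidence predictions correct -> 100%
  pr <- mk_pred(c(0.99, 0.01, 0.6, 0.4), c("GTS", "HC", "HC", "GTS"))
  r <- run_hybrid(pr, 0.9, expert_accuracy = 1, seed = 2)
  expect_equal(r$realized_combined_accuracy, 100)
  expect_equal(r$realized_combined_balanced_accuracy, 100)
  expect_equal(r$n_high, 2)
  expect_equal(r$n_low, 2)
  expect_equal(r$review_fraction, 50)
  # empty review set: report equals the automated-only metrics
  pr2 <- mk_pred(c(0.99, 0.98, 0.01), c("GTS", "GTS", "HC"))
  r2 <- run_hybrid(pr2, 0.9, expert_accuracy = 0.95, seed = 2)
  expect_equal(r2$n_low, 0)
  expect_equal(r2$combined_accuracy, r2$acc_high)
  expect_equal(r2$realized_combined_accuracy, r2$acc_high)
  expect_output(print(r2), "Hybrid")
})

test_that("realized combined accuracy fluctuates around the analytic formula", {
  set.seed(55)
  n_high <- 300; n_low <- 500
  # high-confidence: 90% correct by construction; low: expert with 85% accuracy
  y_high <- rep(c("GTS", "HC"), length.out = n_high)
  p_high <- ifelse(y_high == "GTS", 0.99, 0.01)
  wrong <- seq_len(0.1 * n_high)
  p_high[wrong] <- 1 - p_high[wrong]
  y_low <- rep(c("GTS", "HC"), length.out = n_low)
  p_low <- rep(0.5, n_low)
  pr <- mk_pred(c(p_high, p_low), c(y_high, y_low))
  r <- run_hybrid(pr, 0.9, expert_accuracy = 0.85, seed = 77)
  expect_equal(r$n_high, n_high)
  expect_equal(r$n_low, n_low)
  expect_equal(r$acc_high, 90)
  analytic <- combined_accuracy(n_high, 90, n_low, 85)
  expect_equal(r$combined_accuracy, analytic)
  # only the expert decisions are random
  se <- 100 * sqrt(n_low * 0.85 * 0.15) / (n_high + n_low)
  expect_lt(abs(r$realized_combined_accuracy - analytic), 3 * se)
})

test_that("high-confidence predictions are more accurate on average over seeds", {
  diffs <- c()
  for (seed in 1:20) {
    cohort <- generate_cohort(sim_config(n_pairs = 12, seed = 1000 + seed))
    sc <- tic_scores(cohort)
    fit <- suppressWarnings(ticreg(group ~ proportion_tic_intervals, sc))
    s <- stratify_by_confidence(fit$cv, 0.9)
    if (nrow(s$high) == 0 || nrow(s$low) == 0) next
    diffs <- c(diffs, subgroup_accuracy(s$high) - subgroup_accuracy(s$low))
  }
  expect_gt(length(diffs), 5)
  expect_gt(mean(diffs), 0)
})

test_that("hybrid_sweep tabulates the threshold trade-off", {
  set.seed(2)
  pr <- mk_pred(runif(200), sample(c("GTS", "HC"), 200, replace = TRUE))
  sw <- hybrid_sweep(pr, thresholds = c(0.6, 0.75, 0.9), expert_accuracy = 0.95)
  expect_equal(nrow(sw), 3)
  expect_true(all(diff(sw$n_low) >= 0))
  expect_equal(sw$n_high + sw$n_low, rep(200, 3))
})
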