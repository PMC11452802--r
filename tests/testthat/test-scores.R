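test_that("binarize applies an inclusive 0.5 threshold", {
  expect_identical(binarize(c(0.6, 0.4, 0.5)), c(1L, 0L, 1L))
  expect_identical(binarize(rep(0, 5)), rep(0L, 5))
  expect_error(binarize(numeric(0)), "empty")
  expect_error(binarize(c(0.2, 1.3)), "\\[0, 1\\]")
  expect_error(binarize(0.5, threshold = 1), "threshold")
  set.seed(31)
  p <- runif(1000)
  expect_lt(abs(mean(binarize(p)) - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("run_lengths produces maximal alternating runs that reconstruct the input", {
  expect_equal(run_lengths(c(1, 1, 0, 1)),
               data.frame(value = c(1L, 0L, 1L), length = c(2L, 1L, 1L)))
  expect_equal(run_lengths(c(0, 0, 0)), data.frame(value = 0L, length = 3L))
  set.seed(7)
  for (i in 1:10) {
    x <- rbinom(200, 1, 0.4)
    r <- run_lengths(x)
    expect_identical(rep(r$value, r$length), as.integer(x))  # round trip
    expect_true(all(diff(r$value) != 0))                     # alternation
    expect_true(all(r$length >= 1))
  }
})

test_that("compute_scores matches the direct arithmetic on known patterns", {
  # 3 tic seconds at the start of a 150-s video
  s1 <- compute_scores(c(rep(0.9, 3), rep(0.1, 147)))
  expect_equal(unname(s1), c(2, (3 * 0.9 + 147 * 0.1) / 150, 3, 147, 1 / 2.5))

  # runs of 3, 2 and 4: the run of 2 is not a cluster
  pat <- c(1, 1, 1, 0, 1, 1, 0, 1, 1, 1, 1)
  p <- c(ifelse(pat == 1, 0.8, 0.2), rep(0.1, 150 - length(pat)))
  s2 <- compute_scores(p)
  expect_equal(unname(s2["clusters_per_minute"]), 2 / 2.5)
  expect_equal(unname(s2["max_tic_segment_s"]), 4)
  expect_equal(unname(s2["proportion_tic_intervals"]), 100 * 9 / 150)

  # all-quiescent video
  s3 <- compute_scores(rep(0, 150))
  expect_equal(unname(s3), c(0, 0, 0, 150, 0))
})

test_that("compute_scores agrees with the brute-force per-second oracle", {
  set.seed(99)
  for (i in 1:200) {
    L <- sample(5:200, 1)
    p <- runif(L)
    expect_equal(compute_scores(p), oracle_scores(p))
  }
  # and at a non-default threshold / cluster length
  for (i in 1:25) {
    p <- runif(100)
    expect_equal(compute_scores(p, threshold = 0.3, cluster_min_s = 5),
                 oracle_scores(p, threshold = 0.3, cluster_min = 5))
  }
})

test_that("score properties: monotonicity, cluster bound, degenerate clusters", {
  set.seed(12)
  for (i in 1:30) {
    p <- runif(80)
    s <- compute_scores(p)
    zero_at <- which(p < 0.5)
    if (length(zero_at)) {
      p2 <- p
      p2[sample(zero_at, 1)] <- 0.99  # add one tic interval
      expect_gte(compute_scores(p2)["proportion_tic_intervals"],
                 s["proportion_tic_intervals"])
    }
    # no cluster can exist if the longest tic run is below the minimum
    if (s["max_tic_segment_s"] < 3)
      expect_equal(unname(s["clusters_per_minute"]), 0)
    # structural upper bound on the cluster rate for length L
    L <- length(p)
    expect_lte(s["clusters_per_minute"], floor((L + 1) / 4) / (L / 60))
    expect_lte(s["max_tic_segment_s"] + s["max_ticfree_segment_s"], L)
  }
})

test_that("per-video scores are independent of metadata", {
  cohort <- small_cohort(n_pairs = 3, seed = 17)
  sc <- tic_scores(cohort)
  expect_equal(nrow(sc), nrow(cohort$videos))
  for (v in sc$video_id[1:4]) {
    p <- cohort$probabilities$probability[cohort$probabilities$video_id == v]
    expect_equal(unlist(sc[sc$video_id == v,
                           c("proportion_tic_intervals", "mean_tic_probability",
                             "max_tic_segment_s", "max_ticfree_segment_s",
                             "clusters_per_minute")]),
                 compute_scores(p), ignore_attr = TRUE)
  }
})
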