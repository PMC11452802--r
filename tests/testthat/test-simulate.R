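test_that("cohort generation is deterministic given the seed", {
  cfg <- sim_config(n_pairs = 4, seed = 101)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(sim_config(n_pairs = 4, seed = 102))
  expect_false(identical(a$probabilities$probability, c2$probabilities$probability))
})

test_that("cohort structure: bijective matching and pairwise video balance", {
  for (seed in c(1, 7, 23)) {
    cohort <- generate_cohort(sim_config(n_pairs = 42, video_duration_s = 10,
                                         seed = seed))
    pp <- cohort$participants
    expect_equal(sum(pp$group == "GTS"), 42)
    expect_equal(sum(pp$group == "HC"), 42)
    # partner is in the other group, and partner-of-partner is self
    partner_group <- pp$group[match(pp$matched_partner_id, pp$participant_id)]
    expect_true(all(partner_group != pp$group))
    pop <- pp$matched_partner_id[match(pp$matched_partner_id, pp$participant_id)]
    expect_identical(pop, pp$participant_id)
    # every video's participant exists
    expect_true(all(cohort$videos$participant_id %in% pp$participant_id))
    # matched partners contribute equal numbers of videos
    counts <- table(cohort$videos$participant_id)
    nv <- as.integer(counts[pp$participant_id])
    nv_partner <- as.integer(counts[pp$matched_partner_id])
    expect_equal(nv, nv_partner)
    expect_true(all(nv >= 1 & nv <= 4))
    # per-second rows: one per second per video, 0-based contiguous
    expect_equal(nrow(cohort$probabilities), 10 * nrow(cohort$videos))
    expect_true(all(cohort$probabilities$probability >= 0 &
                    cohort$probabilities$probability <= 1))
  }
})

test_that("hidden chain matches the two-state Markov closed forms", {
  for (pars in list(markov_params(0.05, 0.8), markov_params(0.005, 0.3))) {
    n <- 10000
    set.seed(42)
    sim <- ticscreen:::simulate_series(n, pars)
    pi_tic <- stationary_tic_fraction(pars)
    # Monte-Carlo error of the mean of a 2-state chain: binomial variance
    # inflated by (1 + lambda) / (1 - lambda), lambda the second eigenvalue
    lambda <- pars$p_stay_tic - pars$p_enter_tic
    se <- sqrt(pi_tic * (1 - pi_tic) / n * (1 + lambda) / (1 - lambda))
    expect_lt(abs(mean(sim$hidden) - pi_tic), 3 * se)
    # mean tic run length is geometric: 1 / (1 - p_stay)
    r <- rle(sim$hidden)
    runs <- r$lengths[r$values == 1L]
    expect_gt(length(runs), 10)
    expect_lt(abs(mean(runs) - 1 / (1 - pars$p_stay_tic)),
              3 * stats::sd(runs) / sqrt(length(runs)))
  }
})

test_that("emissions are high in tic seconds and low in quiescent seconds", {
  set.seed(5)
  sim <- ticscreen:::simulate_series(5000, markov_params(0.1, 0.7))
  expect_gt(mean(sim$probability[sim$hidden == 1L]), 0.5)
  expect_lt(mean(sim$probability[sim$hidden == 0L]), 0.5)
  expect_true(all(sim$probability >= 0 & sim$probability <= 1))
})

test_that("simulated expert reproduces labels at the configured accuracy", {
  labels <- rep(c("GTS", "HC"), 5)
  expect_identical(simulate_expert(labels, 1, seed = 1), labels)
  expect_identical(simulate_expert(labels, 0, seed = 1),
                   rep(c("HC", "GTS"), 5))
  big <- rep(c("GTS", "HC"), 5000)
  out <- simulate_expert(big, 0.95, seed = 9)
  agree <- mean(out == big)
  expect_lt(abs(agree - 0.95), 3 * sqrt(0.95 * 0.05 / length(big)))
  # deterministic given seed
  expect_identical(out, simulate_expert(big, 0.95, seed = 9))
})

test_that("invalid configurations raise errors naming the offending field", {
  expect_error(sim_config(n_pairs = 0), "n_pairs")
  expect_error(sim_config(videos_per_participant = c(3, 1)),
               "videos_per_participant")
  expect_error(sim_config(video_duration_s = 0), "video_duration_s")
  expect_error(sim_config(expert_accuracy = 1.2), "expert_accuracy")
  expect_error(markov_params(1.5, 0.5), "p_enter_tic")
  expect_error(markov_params(0.5, 0.5, emission_concentration = -1),
               "emission_concentration")
  expect_error(simulate_expert(c("GTS", "HC"), 1.5, 1), "expert_accuracy")
})
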