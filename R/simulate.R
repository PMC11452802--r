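#' Hidden-state transition and emission parameters for one group
#'
#' Parameters of the two-state (quiescent / tic) hidden Markov process used to
#' simulate a participant's per-second tic dynamics, together with the Beta
#' emission law that turns the hidden state into a noisy per-second tic
#' probability such as an upstream video-based detector would produce.
#'
#' The hidden chain has per-second transition probabilities
#' `p_enter_tic` (quiescent to tic) and `p_stay_tic` (tic to tic), so its
#' stationary tic fraction is `p_enter_tic / (p_enter_tic + 1 - p_stay_tic)`
#' and the mean tic run length is `1 / (1 - p_stay_tic)` seconds. Emitted
#' probabilities are Beta-distributed with mean `mu_tic` in tic seconds and
#' `mu_quiescent` in quiescent seconds; `emission_concentration` is the Beta
#' concentration (shape1 + shape2), so larger values give cleaner traces.
#'
#' @param p_enter_tic Per-second probability of entering the tic state.
#' @param p_stay_tic Per-second probability of remaining in the tic state;
#'   controls burstiness (temporal clustering) of tics.
#' @param emission_concentration Positive Beta concentration of emitted
#'   probabilities around the state mean.
#' @param mu_tic,mu_quiescent Emission means in the tic and quiescent state;
#'   must satisfy `mu_quiescent < mu_tic` and both lie in (0, 1).
#' @return An object of class `"markov_params"`.
#' @seealso [sim_config()], [generate_cohort()]
#' @examples
#' markov_params(p_enter_tic = 0.05, p_stay_tic = 0.8)
#' @export
markov_params <- function(p_enter_tic, p_stay_tic, emission_concentration = 10,
                          mu_tic = 0.8, mu_quiescent = 0.2) {
  p <- list(p_enter_tic = p_enter_tic, p_stay_tic = p_stay_tic,
            emission_concentration = emission_concentration,
            mu_tic = mu_tic, mu_quiescent = mu_quiescent)
  for (nm in c("p_enter_tic", "p_stay_tic", "mu_tic", "mu_quiescent")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("invalid markov_params field '", nm, "': must be a probability in [0, 1]",
           call. = FALSE)
  }
  if (!is.numeric(emission_concentration) || length(emission_concentration) != 1L ||
      !is.finite(emission_concentration) || emission_concentration <= 0)
    stop("invalid markov_params field 'emission_concentration': must be > 0",
         call. = FALSE)
  if (mu_quiescent >= mu_tic)
    stop("invalid markov_params: 'mu_quiescent' must be below 'mu_tic'", call. = FALSE)
  structure(p, class = "markov_params")
}

#' Stationary tic fraction of a two-state hidden chain
#'
#' Closed-form stationary probability of the tic state,
#' `p_enter / (p_enter + 1 - p_stay)`.
#'
#' @param params A [markov_params()] object.
#' @return Stationary tic-state probability in \[0, 1\].
#' @export
stationary_tic_fraction <- function(params) {
  stopifnot(inherits(params, "markov_params"))
  denom <- params$p_enter_tic + 1 - params$p_stay_tic
  if (denom == 0) return(NA_real_)  # absorbing in both states; undefined
  params$p_enter_tic / denom
}

#' Configuration for a synthetic matched GTS/HC cohort
#'
#' Defines the cohort layout and group-level generative parameters used by
#' [generate_cohort()]. Defaults reproduce the reference study design: 42
#' individually matched GTS/HC pairs, one to four 150-second videos per
#' participant, a bursty tic process for the GTS group and a sparse
#' extra-movement process for healthy controls, and a 95%-accurate expert.
#'
#' @param n_pairs Number of matched GTS/HC participant pairs.
#' @param videos_per_participant Integer range `c(min, max)`; each pair's
#'   video count is drawn uniformly from this range and shared by both
#'   partners, preserving pairwise balance.
#' @param video_duration_s Video length in seconds.
#' @param gts,hc [markov_params()] for the two groups.
#' @param participant_sd Standard deviation of the per-participant normal
#'   jitter applied on the log-odds scale to `p_enter_tic`, modelling
#'   between-participant heterogeneity in tic frequency.
#' @param expert_accuracy Probability in \[0, 1\] that a simulated expert
#'   reviewer reproduces the true group label.
#' @param seed Master integer seed; all cohort randomness derives from it.
#' @return An object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_pairs = 5, seed = 1)
#' @export
sim_config <- function(n_pairs = 42,
                       videos_per_participant = c(1L, 4L),
                       video_duration_s = 150,
                       gts = markov_params(0.05, 0.8),
                       hc = markov_params(0.005, 0.3),
                       participant_sd = 0.5,
                       expert_accuracy = 0.95,
                       seed = 1L) {
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || n_pairs < 1 ||
      n_pairs != round(n_pairs))
    stop("invalid sim_config field 'n_pairs': must be a positive integer", call. = FALSE)
  if (!is.numeric(videos_per_participant) || length(videos_per_participant) != 2L ||
      any(videos_per_participant < 1) ||
      videos_per_participant[1] > videos_per_participant[2])
    stop("invalid sim_config field 'videos_per_participant': need c(min, max) with 1 <= min <= max",
         call. = FALSE)
  if (!is.numeric(video_duration_s) || length(video_duration_s) != 1L ||
      video_duration_s < 1 || video_duration_s != round(video_duration_s))
    stop("invalid sim_config field 'video_duration_s': must be a positive integer",
         call. = FALSE)
  if (!inherits(gts, "markov_params"))
    stop("invalid sim_config field 'gts': must be a markov_params object", call. = FALSE)
  if (!inherits(hc, "markov_params"))
    stop("invalid sim_config field 'hc': must be a markov_params object", call. = FALSE)
  if (!is.numeric(participant_sd) || length(participant_sd) != 1L || participant_sd < 0)
    stop("invalid sim_config field 'participant_sd': must be >= 0", call. = FALSE)
  if (!is.numeric(expert_accuracy) || length(expert_accuracy) != 1L ||
      expert_accuracy < 0 || expert_accuracy > 1)
    stop("invalid sim_config field 'expert_accuracy': must be in [0, 1]", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("invalid sim_config field 'seed': must be a finite integer", call. = FALSE)
  structure(list(n_pairs = as.integer(n_pairs),
                 videos_per_participant = as.integer(round(videos_per_participant)),
                 video_duration_s = as.integer(video_duration_s),
                 gts = gts, hc = hc,
                 participant_sd = participant_sd,
                 expert_accuracy = expert_accuracy,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic per-participant substream seed derived from the master seed,
# kept below 2^31 so it is a valid R integer seed.
.substream_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + index * 69621) %% 2147483587L) + 1L
}

#' Simulate one hidden two-state tic chain with Beta-noised emissions
#'
#' @param n_seconds Number of 1-second intervals.
#' @param params A [markov_params()] object (possibly participant-jittered).
#' @return List with integer `hidden` (0 quiescent / 1 tic) and numeric
#'   `probability`, both of length `n_seconds`.
#' @keywords internal
simulate_series <- function(n_seconds, params) {
  pi_tic <- stationary_tic_fraction(params)
  hidden <- integer(n_seconds)
  hidden[1L] <- stats::rbinom(1L, 1L, pi_tic)
  if (n_seconds > 1L) {
    u <- stats::runif(n_seconds - 1L)
    for (t in 2L:n_seconds) {
      p <- if (hidden[t - 1L] == 1L) params$p_stay_tic else params$p_enter_tic
      hidden[t] <- as.integer(u[t - 1L] < p)
    }
  }
  mu <- ifelse(hidden == 1L, params$mu_tic, params$mu_quiescent)
  k <- params$emission_concentration
  probability <- stats::rbeta(n_seconds, mu * k, (1 - mu) * k)
  list(hidden = hidden, probability = probability)
}

#' Generate a synthetic matched GTS/HC cohort of tic-probability series
#'
#' Simulates a cohort of individually matched GTS/healthy-control participant
#' pairs. Each participant's per-second tic dynamics follow a hidden two-state
#' Markov chain (quiescent / tic) with group-specific transition
#' probabilities; the chain starts from its stationary distribution. Each
#' second's emitted probability is drawn from a Beta distribution whose mean
#' is high in tic-state seconds and low in quiescent seconds, emulating the
#' noisy per-second output of a video-based tic detector. Participant-level
#' heterogeneity is introduced by jittering the log-odds of `p_enter_tic` with
#' a normal deviate of standard deviation `participant_sd`. Matched partners
#' always contribute equal numbers of videos.
#'
#' A synthetic "manual tic count" per video — the number of hidden tic-run
#' onsets, i.e. the ground-truth event count of the generator — is included so
#' correlation analyses against manual ratings can be exercised.
#'
#' Generation is fully deterministic given `config$seed`: pair-level layout is
#' drawn from the master seed and each participant uses a deterministic
#' substream seed, so regenerating the same cohort always yields identical
#' data.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `"tic_cohort"`: a list with
#'   \describe{
#'     \item{participants}{data.frame: `participant_id`, `group`,
#'       `matched_partner_id`, `pair_id`.}
#'     \item{videos}{data.frame: `video_id`, `participant_id`, `group`,
#'       `pair_id`, `manual_tic_count`.}
#'     \item{probabilities}{long data.frame: `video_id`, `second_index`
#'       (0-based), `probability`, `hidden_state`.}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' cohort <- generate_cohort(sim_config(n_pairs = 3, seed = 7))
#' cohort
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, config)
  n_pairs <- config$n_pairs
  rng <- config$videos_per_participant
  dur <- config$video_duration_s

  set.seed(config$seed)
  n_videos_pair <- sample.int(rng[2] - rng[1] + 1L, n_pairs, replace = TRUE) + rng[1] - 1L
  jitter_gts <- stats::rnorm(n_pairs, 0, config$participant_sd)
  jitter_hc <- stats::rnorm(n_pairs, 0, config$participant_sd)

  pair_id <- sprintf("P%02d", seq_len(n_pairs))
  gts_id <- sprintf("GTS%02d", seq_len(n_pairs))
  hc_id <- sprintf("HC%02d", seq_len(n_pairs))
  participants <- data.frame(
    participant_id = c(gts_id, hc_id),
    group = rep(c("GTS", "HC"), each = n_pairs),
    matched_partner_id = c(hc_id, gts_id),
    pair_id = rep(pair_id, 2L),
    stringsAsFactors = FALSE)

  jitter_p_enter <- function(base, jit) stats::plogis(stats::qlogis(base) + jit)

  videos <- vector("list", 2L * n_pairs)
  probs <- vector("list", 2L * n_pairs)
  idx <- 0L
  for (i in seq_len(n_pairs)) {
    for (side in c("GTS", "HC")) {
      idx <- idx + 1L
      base <- if (side == "GTS") config$gts else config$hc
      jit <- if (side == "GTS") jitter_gts[i] else jitter_hc[i]
      pp <- base
      pp$p_enter_tic <- jitter_p_enter(base$p_enter_tic, jit)
      pid <- if (side == "GTS") gts_id[i] else hc_id[i]
      set.seed(.substream_seed(config$seed, idx))
      nv <- n_videos_pair[i]
      vids <- sprintf("%s_V%02d", pid, seq_len(nv))
      counts <- integer(nv)
      plist <- vector("list", nv)
      for (v in seq_len(nv)) {
        sim <- simulate_series(dur, pp)
        counts[v] <- sum(diff(c(0L, sim$hidden)) == 1L)
        plist[[v]] <- data.frame(video_id = vids[v],
                                 second_index = 0:(dur - 1L),
                                 probability = sim$probability,
                                 hidden_state = sim$hidden,
                                 stringsAsFactors = FALSE)
      }
      videos[[idx]] <- data.frame(video_id = vids, participant_id = pid,
                                  group = side, pair_id = pair_id[i],
                                  manual_tic_count = counts,
                                  stringsAsFactors = FALSE)
      probs[[idx]] <- do.call(rbind, plist)
    }
  }
  out <- list(participants = participants,
              videos = do.call(rbind, videos),
              probabilities = do.call(rbind, probs),
              config = config)
  rownames(out$videos) <- NULL
  rownames(out$probabilities) <- NULL
  class(out) <- "tic_cohort"
  out
}

#' @export
print.tic_cohort <- function(x, ...) {
  np <- nrow(x$participants) / 2L
  cat("Synthetic matched tic cohort\n")
  cat(sprintf("  %d matched GTS/HC pairs (%d participants), %d videos of %d s\n",
              np, nrow(x$participants), nrow(x$videos), x$config$video_duration_s))
  tab <- table(x$videos$group)
  cat(sprintf("  videos per group: GTS %d, HC %d\n", tab[["GTS"]], tab[["HC"]]))
  cat(sprintf("  seed: %d\n", x$config$seed))
  invisible(x)
}

#' Simulate an expert reviewer's group labels
#'
#' Each true label is reproduced independently with probability
#' `expert_accuracy` and otherwise flipped to the other group, modelling an
#' imperfect human expert reviewing videos. Deterministic given `seed`.
#'
#' @param labels Character vector of group labels (two groups).
#' @param expert_accuracy Probability in \[0, 1\] of reproducing each label.
#' @param seed Integer seed.
#' @param groups Length-2 character vector naming the two groups; labels not
#'   in `groups` are an error.
#' @return Character vector of simulated expert labels, same length as input.
#' @examples
#' simulate_expert(c("GTS", "HC", "GTS"), expert_accuracy = 1, seed = 1)
#' @export
simulate_expert <- function(labels, expert_accuracy, seed,
                            groups = c("GTS", "HC")) {
  if (!is.numeric(expert_accuracy) || length(expert_accuracy) != 1L ||
      expert_accuracy < 0 || expert_accuracy > 1)
    stop("'expert_accuracy' must be a probability in [0, 1]", call. = FALSE)
  labels <- as.character(labels)
  if (!all(labels %in% groups))
    stop("labels contain values outside the declared groups", call. = FALSE)
  if (length(labels) == 0L) return(character(0))
  set.seed(seed)
  keep <- stats::runif(length(labels)) < expert_accuracy
  flipped <- ifelse(labels == groups[1], groups[2], groups[1])
  ifelse(keep, labels, flipped)
}
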