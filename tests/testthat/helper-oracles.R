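# Independent brute-force oracles used to cross-check the implementation.
# Deliberately written as explicit per-element loops, sharing no code with
# the package internals.

oracle_scores <- function(p, threshold = 0.5, cluster_min = 3) {
  L <- length(p)
  b <- integer(L)
  for (i in seq_len(L)) b[i] <- if (p[i] >= threshold) 1L else 0L
  n_tic <- 0L
  for (i in seq_len(L)) n_tic <- n_tic + b[i]
  max_tic <- 0L; max_free <- 0L; clusters <- 0L
  cur <- 0L; curval <- -1L
  close_run <- function() {
    if (curval == 1L) {
      if (cur >= cluster_min) clusters <<- clusters + 1L
      if (cur > max_tic) max_tic <<- cur
    } else if (curval == 0L) {
      if (cur > max_free) max_free <<- cur
    }
  }
  for (i in seq_len(L)) {
    if (b[i] == curval) {
      cur <- cur + 1L
    } else {
      close_run()
      curval <- b[i]
      cur <- 1L
    }
  }
  close_run()
  c(proportion_tic_intervals = 100 * n_tic / L,
    mean_tic_probability = sum(p) / L,
    max_tic_segment_s = as.numeric(max_tic),
    max_ticfree_segment_s = as.numeric(max_free),
    clusters_per_minute = clusters / (L / 60))
}

# exhaustive O(n^2) Mann-Whitney count, ties counted one half
oracle_auroc <- function(p, is_pos) {
  pos <- p[is_pos]; neg <- p[!is_pos]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# confusion-matrix balanced accuracy, predicted positive iff p >= thr
oracle_balanced_accuracy <- function(p, is_pos, thr = 0.5) {
  tp <- sum(p >= thr & is_pos); fn <- sum(p < thr & is_pos)
  tn <- sum(p < thr & !is_pos); fp <- sum(p >= thr & !is_pos)
  100 * (tp / (tp + fn) + tn / (tn + fp)) / 2
}

small_cohort <- function(n_pairs = 6, seed = 11, ...) {
  generate_cohort(sim_config(n_pairs = n_pairs, seed = seed, ...))
}
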