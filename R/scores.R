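#' Binarize a per-second tic-probability series
#'
#' A 1-second interval is a "tic interval" when its detector probability
#' meets the detection threshold. The tie at exactly the threshold counts as
#' a tic (inclusive `>=`).
#'
#' @param probabilities Numeric vector of per-second probabilities in \[0, 1\].
#' @param threshold Detection threshold in (0, 1); default 0.5.
#' @return Integer vector of 0/1 tic indicators, same length as input.
#' @examples
#' binarize(c(0.6, 0.4, 0.5))
#' @export
binarize <- function(probabilities, threshold = 0.5) {
  if (length(probabilities) == 0L)
    stop("empty probability series", call. = FALSE)
  if (!is.numeric(probabilities) || anyNA(probabilities) ||
      any(probabilities < 0 | probabilities > 1))
    stop("probabilities must be in [0, 1]", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie in (0, 1)", call. = FALSE)
  as.integer(probabilities >= threshold)
}

#' Run-length encode a binary tic series
#'
#' Maximal runs of equal values in order; the shared kernel behind the
#' segment-duration and cluster scores.
#'
#' @param x Vector of 0/1 tic indicators.
#' @return data.frame with columns `value` (0 or 1) and `length` (positive
#'   integer); lengths sum to `length(x)` and adjacent runs alternate.
#' @examples
#' run_lengths(c(1, 1, 0, 1))
#' @export
run_lengths <- function(x) {
  if (length(x) == 0L) stop("empty series", call. = FALSE)
  if (anyNA(x) || !all(x %in% c(0, 1)))
    stop("series must contain only 0 and 1", call. = FALSE)
  r <- rle(as.integer(x))
  data.frame(value = r$values, length = r$lengths)
}

#' Compute the five tic summary scores for one video
#'
#' From a per-second tic-probability series, computes:
#' \enumerate{
#'   \item `proportion_tic_intervals` — percentage of 1-second intervals at or
#'     above the detection threshold;
#'   \item `mean_tic_probability` — arithmetic mean of the raw probabilities;
#'   \item `max_tic_segment_s` — longest run of consecutive tic intervals
#'     (seconds; 0 if none);
#'   \item `max_ticfree_segment_s` — longest run of consecutive tic-free
#'     intervals (seconds; 0 if none);
#'   \item `clusters_per_minute` — number of maximal tic runs of at least
#'     `cluster_min_s` seconds, per minute of video.
#' }
#' Clusters are purely run-based: runs touching the video boundary count, and
#' two runs separated by a single tic-free second are two clusters. Rates are
#' normalized by the actual video length, so series of any duration are
#' accepted.
#'
#' @param probabilities Numeric vector of per-second probabilities in \[0, 1\].
#' @param threshold Tic-detection threshold; see [binarize()].
#' @param cluster_min_s Minimum run length (seconds) for a tic cluster.
#' @return Named numeric vector with the five scores.
#' @examples
#' compute_scores(c(rep(0.9, 3), rep(0.1, 147)))
#' @export
compute_scores <- function(probabilities, threshold = 0.5, cluster_min_s = 3L) {
  b <- binarize(probabilities, threshold)
  if (!is.numeric(cluster_min_s) || length(cluster_min_s) != 1L || cluster_min_s < 1)
    stop("'cluster_min_s' must be a positive integer", call. = FALSE)
  L <- length(b)
  runs <- run_lengths(b)
  tic_runs <- runs$length[runs$value == 1L]
  free_runs <- runs$length[runs$value == 0L]
  c(proportion_tic_intervals = 100 * sum(b) / L,
    mean_tic_probability = mean(probabilities),
    max_tic_segment_s = if (length(tic_runs)) max(tic_runs) else 0,
    max_ticfree_segment_s = if (length(free_runs)) max(free_runs) else 0,
    clusters_per_minute = sum(tic_runs >= cluster_min_s) / (L / 60))
}

#' Tic summary scores for every video of a cohort or probability table
#'
#' Applies [compute_scores()] per video and returns one row per video. For a
#' [generate_cohort()] object the participant, group, pair and synthetic
#' manual-count metadata are carried along; for a long-format probability
#' table (columns `video_id`, `second_index`, `probability`) only `video_id`
#' is attached.
#'
#' @param x A `"tic_cohort"` object or a long-format probability data.frame.
#' @param threshold,cluster_min_s Passed to [compute_scores()].
#' @param ... Unused.
#' @return data.frame of per-video scores, class `"tic_scores"`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_pairs = 2, seed = 1))
#' head(tic_scores(cohort))
#' @export
tic_scores <- function(x, threshold = 0.5, cluster_min_s = 3L, ...) {
  UseMethod("tic_scores")
}

#' @rdname tic_scores
#' @export
tic_scores.tic_cohort <- function(x, threshold = 0.5, cluster_min_s = 3L, ...) {
  sc <- tic_scores(x$probabilities, threshold = threshold,
                   cluster_min_s = cluster_min_s)
  out <- merge(x$videos, sc, by = "video_id", sort = FALSE)
  out <- out[match(x$videos$video_id, out$video_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tic_scores", "data.frame")
  out
}

#' @rdname tic_scores
#' @export
tic_scores.data.frame <- function(x, threshold = 0.5, cluster_min_s = 3L, ...) {
  need <- c("video_id", "second_index", "probability")
  if (!all(need %in% names(x)))
    stop("probability table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x <- x[order(x$video_id, x$second_index), , drop = FALSE]
  ids <- unique(x$video_id)
  rows <- lapply(ids, function(v) {
    p <- x$probability[x$video_id == v]
    as.data.frame(c(list(video_id = v),
                    as.list(compute_scores(p, threshold, cluster_min_s))),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tic_scores", "data.frame")
  out
}
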