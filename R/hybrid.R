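# Hybrid human/machine decision scheme: accept high-confidence automated
# predictions, route the rest to (simulated) expert review.

#' Split predictions by automated confidence
#'
#' A prediction is high-confidence when `max(p_gts, 1 - p_gts)` strictly
#' exceeds the confidence threshold, i.e. the model favors one group with
#' probability above the threshold; a probability exactly at the threshold is
#' low-confidence. The two subsets partition the input.
#'
#' @param predictions A `"cv_predictions"` data.frame (or any data.frame with
#'   `p_gts`, `true_group`).
#' @param confidence_threshold Threshold in \[0.5, 1); default 0.9.
#' @return List with data.frames `high` and `low`.
#' @examples
#' pr <- data.frame(video_id = 1:3, true_group = c("GTS", "HC", "GTS"),
#'                  p_gts = c(0.95, 0.05, 0.5))
#' stratify_by_confidence(pr)
#' @export
stratify_by_confidence <- function(predictions, confidence_threshold = 0.9) {
  if (!is.numeric(confidence_threshold) || length(confidence_threshold) != 1L ||
      confidence_threshold < 0.5 || confidence_threshold >= 1)
    stop("'confidence_threshold' must lie in [0.5, 1)", call. = FALSE)
  if (!"p_gts" %in% names(predictions))
    stop("predictions must contain a 'p_gts' column", call. = FALSE)
  conf <- pmax(predictions$p_gts, 1 - predictions$p_gts)
  high <- conf > confidence_threshold
  list(high = predictions[high, , drop = FALSE],
       low = predictions[!high, , drop = FALSE])
}

#' Plain classification accuracy within a prediction subset
#'
#' Fraction of videos whose automated classification (GTS iff
#' `p_gts >= decision_threshold`) matches the true group, in percent.
#'
#' @param subset Nonempty predictions data.frame (`p_gts`, `true_group`).
#' @param decision_threshold Classification threshold, default 0.5.
#' @param positive Positive-class label.
#' @return Accuracy in percent.
#' @export
subgroup_accuracy <- function(subset, decision_threshold = 0.5, positive = "GTS") {
  if (NROW(subset) == 0L) stop("empty prediction subset", call. = FALSE)
  v <- .as_pred_vectors(subset, NULL, positive)
  100 * mean((v$p >= decision_threshold) == v$y)
}

#' Expert review burden
#'
#' Percentage of videos routed to expert review.
#'
#' @param n_low Number of low-confidence predictions.
#' @param n_total Total number of predictions (> 0).
#' @return Percentage `100 * n_low / n_total`.
#' @examples
#' review_burden(71, 214)
#' @export
review_burden <- function(n_low, n_total) {
  if (!is.numeric(n_total) || n_total <= 0)
    stop("'n_total' must be positive", call. = FALSE)
  if (!is.numeric(n_low) || n_low < 0 || n_low > n_total)
    stop("'n_low' must lie in [0, n_total]", call. = FALSE)
  100 * n_low / n_total
}

#' Analytic combined accuracy of the hybrid scheme
#'
#' Weighted mean of the automated accuracy on high-confidence predictions and
#' the assumed expert accuracy on reviewed (low-confidence) predictions:
#' `(n_high * acc_high + n_low * expert_accuracy) / (n_high + n_low)`.
#'
#' @param n_high,n_low Subgroup sizes (not both zero).
#' @param acc_high Automated accuracy on the high-confidence subgroup, in
#'   percent.
#' @param expert_accuracy Assumed expert accuracy, in percent.
#' @return Combined accuracy in percent.
#' @examples
#' combined_accuracy(143, 97.9, 71, 95)
#' @export
combined_accuracy <- function(n_high, acc_high, n_low, expert_accuracy) {
  if (n_high < 0 || n_low < 0 || (n_high + n_low) == 0)
    stop("subgroup sizes must be nonnegative and not both zero", call. = FALSE)
  for (a in c(acc_high, expert_accuracy))
    if (!is.numeric(a) || a < 0 || a > 100)
      stop("accuracies must be percentages in [0, 100]", call. = FALSE)
  (n_high * acc_high + n_low * expert_accuracy) / (n_high + n_low)
}

#' Evaluate the hybrid human/machine decision scheme
#'
#' Stratifies cross-validated predictions by confidence, keeps the automated
#' classification for high-confidence videos, simulates an expert review
#' (label noise with the given accuracy) for low-confidence videos, and
#' reports subgroup accuracies, the review burden, the analytic combined
#' accuracy, and the empirically realized combined plain and balanced
#' accuracies of the hybrid decisions.
#'
#' @param predictions A `"cv_predictions"` data.frame or a `"ticreg"` fit
#'   (its cross-validated predictions are used).
#' @param confidence_threshold Confidence threshold in \[0.5, 1).
#' @param expert_accuracy Expert accuracy as a probability in \[0, 1\]
#'   (default 0.95).
#' @param seed Integer seed for the simulated expert.
#' @param decision_threshold Automated classification threshold.
#' @param positive Positive-class label.
#' @return Object of class `"hybrid_report"`: list with fields
#'   `confidence_threshold`, `n_total`, `n_high`, `n_low`, `review_fraction`,
#'   `acc_high`, `acc_low`, `expert_accuracy` (percent),
#'   `combined_accuracy` (analytic), `realized_combined_accuracy`,
#'   `realized_combined_balanced_accuracy`, and the hybrid per-video
#'   decisions in `decisions`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_pairs = 8, seed = 4))
#' fit <- ticreg(group ~ clusters_per_minute, tic_scores(cohort))
#' run_hybrid(fit, seed = 1)
#' @export
run_hybrid <- function(predictions, confidence_threshold = 0.9,
                       expert_accuracy = 0.95, seed = 1L,
                       decision_threshold = 0.5, positive = "GTS") {
  if (inherits(predictions, "ticreg")) predictions <- predictions$cv
  if (NROW(predictions) == 0L) stop("no predictions supplied", call. = FALSE)
  if (expert_accuracy < 0 || expert_accuracy > 1)
    stop("'expert_accuracy' must be a probability in [0, 1]", call. = FALSE)
  strata <- stratify_by_confidence(predictions, confidence_threshold)
  high <- strata$high; low <- strata$low
  n_high <- nrow(high); n_low <- nrow(low); n_total <- n_high + n_low

  groups <- sort(unique(as.character(predictions$true_group)))
  negative <- setdiff(groups, positive)[1]
  auto_label <- function(d)
    ifelse(d$p_gts >= decision_threshold, positive, negative)

  acc_high <- if (n_high > 0) subgroup_accuracy(high, decision_threshold, positive) else NA_real_
  acc_low <- if (n_low > 0) subgroup_accuracy(low, decision_threshold, positive) else NA_real_

  decisions <- predictions[, intersect(c("video_id", "true_group", "p_gts", "fold_id"),
                                       names(predictions)), drop = FALSE]
  conf <- pmax(predictions$p_gts, 1 - predictions$p_gts)
  is_high <- conf > confidence_threshold
  decisions$source <- ifelse(is_high, "automated", "expert")
  decisions$decision <- NA_character_
  decisions$decision[is_high] <- auto_label(predictions[is_high, , drop = FALSE])
  if (n_low > 0)
    decisions$decision[!is_high] <- simulate_expert(
      as.character(predictions$true_group)[!is_high], expert_accuracy, seed,
      groups = c(positive, negative))

  correct <- decisions$decision == as.character(predictions$true_group)
  realized <- 100 * mean(correct)
  y <- as.character(predictions$true_group) == positive
  realized_bal <- if (any(y) && any(!y))
    100 * (mean(correct[y]) + mean(correct[!y])) / 2 else NA_real_

  analytic <- combined_accuracy(n_high,
                                if (n_high > 0) acc_high else 0,
                                n_low, 100 * expert_accuracy)

  structure(list(confidence_threshold = confidence_threshold,
                 n_total = n_total, n_high = n_high, n_low = n_low,
                 review_fraction = review_burden(n_low, n_total),
                 acc_high = acc_high, acc_low = acc_low,
                 expert_accuracy = 100 * expert_accuracy,
                 combined_accuracy = analytic,
                 realized_combined_accuracy = realized,
                 realized_combined_balanced_accuracy = realized_bal,
                 decisions = decisions),
            class = "hybrid_report")
}

#' @export
print.hybrid_report <- function(x, ...) {
  cat("Hybrid human/machine diagnostic evaluation\n")
  cat(sprintf("  confidence threshold: %.2f   expert accuracy: %.1f%%\n",
              x$confidence_threshold, x$expert_accuracy))
  cat(sprintf("  high-confidence: %d of %d videos, accuracy %s\n",
              x$n_high, x$n_total,
              if (is.na(x$acc_high)) "-" else sprintf("%.1f%%", x$acc_high)))
  cat(sprintf("  reviewed (low-confidence): %d of %d videos (%.1f%%), automated accuracy %s\n",
              x$n_low, x$n_total, x$review_fraction,
              if (is.na(x$acc_low)) "-" else sprintf("%.1f%%", x$acc_low)))
  cat(sprintf("  combined accuracy: analytic %.2f%%, realized %.2f%% (balanced %.2f%%)\n",
              x$combined_accuracy, x$realized_combined_accuracy,
              x$realized_combined_balanced_accuracy))
  invisible(x)
}

#' Sweep the confidence threshold of the hybrid scheme
#'
#' Evaluates [run_hybrid()] over a grid of confidence thresholds and returns
#' a table of review burden and accuracies per threshold.
#'
#' @inheritParams run_hybrid
#' @param thresholds Numeric vector of confidence thresholds in \[0.5, 1).
#' @return data.frame with one row per threshold: `threshold`, `n_high`,
#'   `n_low`, `review_fraction`, `acc_high`, `acc_low`, `combined_accuracy`,
#'   `realized_combined_accuracy`, `realized_combined_balanced_accuracy`.
#' @export
hybrid_sweep <- function(predictions, thresholds = seq(0.5, 0.95, by = 0.05),
                         expert_accuracy = 0.95, seed = 1L,
                         decision_threshold = 0.5, positive = "GTS") {
  rows <- lapply(thresholds, function(th) {
    r <- run_hybrid(predictions, th, expert_accuracy, seed,
                    decision_threshold, positive)
    data.frame(threshold = th, n_high = r$n_high, n_low = r$n_low,
               review_fraction = r$review_fraction,
               acc_high = r$acc_high, acc_low = r$acc_low,
               combined_accuracy = r$combined_accuracy,
               realized_combined_accuracy = r$realized_combined_accuracy,
               realized_combined_balanced_accuracy = r$realized_combined_balanced_accuracy)
  })
  do.call(rbind, rows)
}
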