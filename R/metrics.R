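# Classification metrics for cross-validated GTS-vs-HC predictions.
# All of them accept either (p, labels) vectors or a predictions data.frame
# with columns p_gts / true_group, as produced by leave_pair_out_cv().

.as_pred_vectors <- function(p, labels, positive = "GTS") {
  if (is.data.frame(p)) {
    if (!all(c("p_gts", "true_group") %in% names(p)))
      stop("predictions data.frame needs columns 'p_gts' and 'true_group'",
           call. = FALSE)
    labels <- p$true_group
    p <- p$p_gts
  }
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("predicted probabilities must be in [0, 1]", call. = FALSE)
  list(p = as.numeric(p), y = as.character(labels) == positive)
}

#' Balanced classification accuracy
#'
#' Arithmetic mean of sensitivity (GTS videos classified GTS) and specificity
#' (HC videos classified HC), as a percentage; robust to class imbalance.
#' A video is classified GTS when its predicted probability is at or above
#' the decision threshold (ties go to GTS).
#'
#' @param p Numeric vector of predicted GTS probabilities, or a predictions
#'   data.frame with columns `p_gts` and `true_group`.
#' @param labels True group labels (ignored when `p` is a data.frame).
#' @param decision_threshold Classification threshold, default 0.5.
#' @param positive Positive-class label, default "GTS".
#' @return Balanced accuracy in percent.
#' @examples
#' balanced_accuracy(c(0.9, 0.8, 0.1, 0.6), c("GTS", "GTS", "HC", "HC"))
#' @export
balanced_accuracy <- function(p, labels = NULL, decision_threshold = 0.5,
                              positive = "GTS") {
  v <- .as_pred_vectors(p, labels, positive)
  if (!any(v$y) || all(v$y))
    stop("both classes must be present to compute balanced accuracy",
         call. = FALSE)
  pred <- v$p >= decision_threshold
  sens <- mean(pred[v$y])
  spec <- mean(!pred[!v$y])
  100 * (sens + spec) / 2
}

#' ROC curve and AUROC
#'
#' Computes the receiver-operating-characteristic curve over all observed
#' score thresholds (classified positive at probability >= threshold) and the
#' area under it. The AUROC equals the Mann–Whitney probability that a
#' randomly chosen GTS video's score exceeds a randomly chosen HC video's,
#' with ties counted one half; it is computed from midranks and is therefore
#' invariant under strictly monotone transforms of the scores.
#'
#' @inheritParams balanced_accuracy
#' @return Object of class `"roc_result"`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auroc`, `n_positive`, `n_negative`.
#' @examples
#' roc_auroc(c(0.9, 0.8, 0.2, 0.4), c("GTS", "GTS", "HC", "HC"))$auroc
#' @export
roc_auroc <- function(p, labels = NULL, positive = "GTS") {
  v <- .as_pred_vectors(p, labels, positive)
  n1 <- sum(v$y); n0 <- sum(!v$y)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  r <- rank(v$p)  # midranks: ties contribute 1/2
  auroc <- (sum(r[v$y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(sort(unique(v$p)), Inf)
  sens <- vapply(thr, function(t) mean(v$p[v$y] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(v$p[!v$y] < t), numeric(1))
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auroc = auroc, n_positive = n1, n_negative = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUROC = %.4f (%d positive, %d negative videos)\n",
              x$auroc, x$n_positive, x$n_negative))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUROC = %.3f", x$auroc))
  invisible(x)
}

#' Correlation between an automated score and manual tic ratings
#'
#' Pearson product-moment correlation (default) between a per-video summary
#' score and manually rated tic counts; Spearman rank correlation available
#' via `method`.
#'
#' @param scores Numeric per-video score values.
#' @param manual_counts Numeric per-video manual tic counts.
#' @param method "pearson" (default) or "spearman".
#' @return Correlation coefficient in \[-1, 1\].
#' @examples
#' score_rating_correlation(1:10, 2 * (1:10))
#' @export
score_rating_correlation <- function(scores, manual_counts,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(scores) != length(manual_counts))
    stop("'scores' and 'manual_counts' must have equal length", call. = FALSE)
  if (length(scores) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(scores) == 0 || stats::sd(manual_counts) == 0)
    stop("zero variance in scores or manual counts", call. = FALSE)
  stats::cor(scores, manual_counts, method = method)
}
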