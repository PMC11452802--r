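#' Leave-pair-out cross-validated GTS probabilities
#'
#' For each matched participant pair, fits the logistic model on all videos
#' excluding every video from both pair members, then predicts the held-out
#' videos. Each video therefore receives exactly one cross-validated GTS
#' probability, from a model that never saw the video's participant or their
#' individually matched partner — preserving group matching and avoiding
#' class-imbalance bias.
#'
#' @param formula Model formula, e.g.
#'   `group ~ proportion_tic_intervals` or a multi-score right-hand side. The
#'   response is the group label.
#' @param data Per-video data.frame (e.g. from [tic_scores()]) containing the
#'   response, the predictors, and ideally a `video_id` column.
#' @param pair Fold identifier: a vector with one element per row of `data`,
#'   or the name of a column of `data` (default `"pair_id"`). All videos
#'   sharing a pair id form one held-out fold.
#' @param ridge Ridge stabilizer passed to [fit_logistic()].
#' @param positive Positive-class label (default "GTS").
#' @param standardize Z-score the predictors using each training fold's mean
#'   and standard deviation (no information leaks from held-out videos).
#' @return data.frame of class `"cv_predictions"` with columns `video_id`,
#'   `true_group`, `p_gts`, `fold_id`, plus attributes `n_separation`
#'   (number of folds with flagged separation) and `positive`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_pairs = 6, seed = 2))
#' sc <- tic_scores(cohort)
#' cv <- leave_pair_out_cv(group ~ clusters_per_minute, sc)
#' head(cv)
#' @export
leave_pair_out_cv <- function(formula, data, pair = "pair_id", ridge = 1e-6,
                              positive = "GTS", standardize = FALSE) {
  data <- as.data.frame(data)
  if (is.character(pair) && length(pair) == 1L) {
    if (!pair %in% names(data))
      stop("pair column '", pair, "' not found in data", call. = FALSE)
    pair <- data[[pair]]
  }
  if (length(pair) != nrow(data))
    stop("'pair' must supply one fold id per video", call. = FALSE)
  mf <- stats::model.frame(formula, data)
  y <- as.character(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)[, -1L, drop = FALSE]
  video_id <- if ("video_id" %in% names(data)) as.character(data$video_id)
              else rownames(data)

  folds <- unique(pair)
  p_out <- rep(NA_real_, nrow(data))
  n_sep <- 0L
  for (f in folds) {
    hold <- pair == f
    ytr <- y[!hold]
    if (length(unique(ytr)) < 2L)
      stop("training data for fold '", f, "' contains a single class",
           call. = FALSE)
    Xtr <- X[!hold, , drop = FALSE]
    Xte <- X[hold, , drop = FALSE]
    if (standardize && ncol(X)) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
    }
    fit <- fit_logistic(Xtr, ytr, ridge = ridge, positive = positive,
                        warn = FALSE)
    n_sep <- n_sep + fit$separation
    p_out[hold] <- predict(fit, Xte)
  }
  if (n_sep > 0L)
    warning(n_sep, " of ", length(folds),
            " cross-validation folds showed complete separation (ridge-stabilized)",
            call. = FALSE)
  out <- data.frame(video_id = video_id, true_group = y, p_gts = p_out,
                    fold_id = as.character(pair), stringsAsFactors = FALSE)
  attr(out, "n_separation") <- n_sep
  attr(out, "positive") <- positive
  class(out) <- c("cv_predictions", "data.frame")
  out
}

#' Cross-validated logistic classification of videos (GTS vs HC)
#'
#' The package's central model: a binomial logistic regression of clinical
#' group on per-video tic summary scores, evaluated by matched-pair
#' leave-pair-out cross-validation. The returned object carries the full-data
#' fit (for coefficients and prediction on new videos), the per-video
#' cross-validated GTS probabilities, and video-level performance metrics
#' (balanced accuracy and AUROC computed from the cross-validated
#' probabilities).
#'
#' @inheritParams leave_pair_out_cv
#' @param decision_threshold Probability threshold for classifying a video as
#'   GTS (ties go to GTS).
#' @return Object of class `"ticreg"`: list with `model` (the full-data
#'   [fit_logistic()] fit), `cv` (a `"cv_predictions"` data.frame),
#'   `balanced_accuracy`, `roc` (a `"roc_result"`), `formula`, `data`,
#'   `decision_threshold`, `n_videos`, `n_folds`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_pairs = 8, seed = 3))
#' fit <- ticreg(group ~ proportion_tic_intervals, tic_scores(cohort))
#' fit
#' coef(fit)
#' @export
ticreg <- function(formula, data, pair = "pair_id", ridge = 1e-6,
                   decision_threshold = 0.5, positive = "GTS",
                   standardize = FALSE) {
  data <- as.data.frame(data)
  cv <- leave_pair_out_cv(formula, data, pair = pair, ridge = ridge,
                          positive = positive, standardize = standardize)
  mf <- stats::model.frame(formula, data)
  y <- as.character(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)[, -1L, drop = FALSE]
  if (standardize && ncol(X))
    X <- scale(X)
  full <- fit_logistic(X, y, ridge = ridge, positive = positive, warn = FALSE)
  structure(list(model = full,
                 cv = cv,
                 balanced_accuracy = balanced_accuracy(cv, decision_threshold = decision_threshold,
                                                       positive = positive),
                 roc = roc_auroc(cv, positive = positive),
                 formula = formula,
                 data = data,
                 decision_threshold = decision_threshold,
                 positive = positive,
                 standardize = standardize,
                 n_videos = nrow(data),
                 n_folds = length(unique(cv$fold_id))),
            class = "ticreg")
}

#' @export
print.ticreg <- function(x, digits = 3, ...) {
  cat("Leave-pair-out cross-validated logistic classification\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  %d videos, %d matched-pair folds\n", x$n_videos, x$n_folds))
  cat(sprintf("  cross-validated balanced accuracy: %.1f%%  AUROC: %.3f\n",
              x$balanced_accuracy, x$roc$auroc))
  cat("  coefficients (full-data fit):\n")
  print(round(coef(x$model), digits))
  invisible(x)
}

#' @export
summary.ticreg <- function(object, ...) {
  cf <- coef(object$model)
  se <- sqrt(diag(object$model$vcov))
  z <- cf / se
  tab <- cbind(Estimate = cf, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(call_formula = object$formula, coefficients = tab,
              balanced_accuracy = object$balanced_accuracy,
              auroc = object$roc$auroc, n_videos = object$n_videos,
              n_folds = object$n_folds,
              n_separation = attr(object$cv, "n_separation"),
              loglik = object$model$loglik,
              converged = object$model$converged)
  class(out) <- "summary.ticreg"
  out
}

#' @export
print.summary.ticreg <- function(x, ...) {
  cat("Leave-pair-out cross-validated logistic classification\n")
  cat("  ", deparse(x$call_formula), "\n\n", sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nVideos: %d   folds: %d   log-likelihood (full fit): %.3f\n",
              x$n_videos, x$n_folds, x$loglik))
  cat(sprintf("Cross-validated balanced accuracy: %.1f%%   AUROC: %.3f\n",
              x$balanced_accuracy, x$auroc))
  if (x$n_separation > 0)
    cat(sprintf("Note: %d fold(s) showed complete separation (ridge-stabilized)\n",
                x$n_separation))
  invisible(x)
}

#' @export
coef.ticreg <- function(object, ...) coef(object$model)

#' @export
vcov.ticreg <- function(object, ...) object$model$vcov

#' @export
logLik.ticreg <- function(object, ...) logLik(object$model)

#' Predict GTS probabilities for new videos
#'
#' Uses the full-data fit; omit `newdata` to retrieve the cross-validated
#' probabilities (`type = "cv"`, the default) or the in-sample fitted
#' probabilities (`type = "response"`).
#'
#' @param object A `"ticreg"` fit.
#' @param newdata Optional data.frame of new per-video scores.
#' @param type For `newdata = NULL`: `"cv"` or `"response"`.
#' @param ... Unused.
#' @return Numeric vector of GTS probabilities.
#' @export
predict.ticreg <- function(object, newdata = NULL, type = c("cv", "response"), ...) {
  if (is.null(newdata)) {
    type <- match.arg(type)
    if (type == "cv") return(object$cv$p_gts)
    newdata <- object$data
  }
  mf <- stats::model.frame(stats::delete.response(stats::terms(object$formula)),
                           as.data.frame(newdata))
  X <- stats::model.matrix(attr(mf, "terms"), mf)[, -1L, drop = FALSE]
  if (object$standardize && ncol(X)) {
    mf0 <- stats::model.frame(object$formula, object$data)
    X0 <- stats::model.matrix(attr(mf0, "terms"), mf0)[, -1L, drop = FALSE]
    X <- sweep(sweep(X, 2, colMeans(X0)), 2, apply(X0, 2, stats::sd), "/")
  }
  predict(object$model, X)
}

#' @export
fitted.ticreg <- function(object, ...) predict(object, type = "response")

#' @export
residuals.ticreg <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  y <- as.integer(object$cv$true_group == object$positive)
  mu <- fitted(object)
  if (type == "response") return(y - mu)
  d <- -2 * (y * log(mu) + (1 - y) * log(1 - mu))
  sign(y - mu) * sqrt(pmax(d, 0))
}

#' @export
plot.ticreg <- function(x, ...) {
  plot(x$roc, main = deparse(x$formula), ...)
}

#' Simulate group labels from the fitted video-level probabilities
#'
#' Draws Bernoulli group labels from the model's in-sample fitted GTS
#' probabilities, one column per replicate — a parametric-bootstrap view of
#' the classifier's own uncertainty.
#'
#' @param object A `"ticreg"` fit.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return data.frame of simulated labels, `nsim` columns.
#' @export
simulate.ticreg <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  negative <- setdiff(unique(object$cv$true_group), object$positive)[1]
  out <- as.data.frame(replicate(nsim, ifelse(stats::runif(length(mu)) < mu,
                                              object$positive, negative),
                                 simplify = FALSE),
                       col.names = paste0("sim_", seq_len(nsim)))
  rownames(out) <- object$cv$video_id
  out
}
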