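#' Fit a (optionally ridge-stabilized) binomial logistic regression
#'
#' Maximizes the binomial log-likelihood by iteratively reweighted least
#' squares (Newton steps with step-halving), with an optional tiny quadratic
#' penalty `ridge * sum(beta_j^2)` on the slope coefficients (never the
#' intercept) for numerical stability when the training data are separable.
#' Convergence is declared when the penalized gradient norm falls below
#' `tol`; otherwise the fit is flagged non-converged. A complete-separation
#' flag is set when every observation is fitted essentially exactly.
#'
#' @param x Numeric matrix (or data.frame) of predictors, one column per
#'   score, without an intercept column.
#' @param y Binary response: logical, 0/1 numeric, or a vector of group
#'   labels with `positive` naming the positive class.
#' @param ridge Nonnegative ridge penalty; default `1e-6`, set 0 for the
#'   plain maximum-likelihood fit.
#' @param positive Label coded 1 when `y` is not already 0/1 (default "GTS").
#' @param tol Gradient-norm convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @param warn Emit warnings for separation / non-convergence.
#' @return Object of class `"logistic_model"` with elements `coefficients`
#'   (intercept first), `vcov`, `loglik`, `converged`, `separation`,
#'   `iterations`, `predictor_names`, `ridge`.
#' @examples
#' x <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1,
#'             dimnames = list(NULL, "score"))
#' y <- c(rep(c(1, 0), c(2, 8)), rep(c(1, 0), c(8, 2)))
#' coef(fit_logistic(x, y, ridge = 0))
#' @export
fit_logistic <- function(x, y, ridge = 1e-6, positive = "GTS",
                         tol = 1e-8, max_iter = 100L, warn = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("predictors must be numeric", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite predictor value", call. = FALSE)
  if (ncol(x) > 0L && is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.logical(y)) y <- as.integer(y)
  if (!is.numeric(y)) y <- as.integer(as.character(y) == positive)
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("response must be binary", call. = FALSE)
  if (length(y) != nrow(x)) stop("x and y lengths differ", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training data", call. = FALSE)
  if (!is.numeric(ridge) || length(ridge) != 1L || ridge < 0)
    stop("'ridge' must be nonnegative", call. = FALSE)

  X <- cbind("(Intercept)" = 1, x)
  p <- ncol(X)
  pen <- c(0, rep(ridge, p - 1L))
  beta <- numeric(p)

  # overflow-safe log(1 + exp(eta))
  log1pexp <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))
  pen_loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1pexp(eta)) - sum(pen * b^2)
  }

  converged <- FALSE
  iter <- 0L
  H <- NULL
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu)) - 2 * pen * beta
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; iter <- iter - 1L; break }
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * w) + diag(2 * pen, p)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) step <- drop(qr.solve(H + diag(1e-8, p), grad))
    ll0 <- pen_loglik(beta)
    s <- 1
    repeat {  # step-halving keeps Newton stable on near-separated data
      cand <- beta + s * step
      if (pen_loglik(cand) >= ll0 - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    beta <- cand
    if (iter >= max_iter) break
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  # with a tiny ridge, separated data converge to a near-perfect fit whose
  # residuals are O(ridge * |beta|); 1e-3 distinguishes that from genuine
  # probabilistic fits, where at least one residual stays O(1)
  separation <- all(abs(y - mu) < 1e-3)
  w <- pmax(mu * (1 - mu), 1e-12)
  Hfinal <- crossprod(X, X * w) + diag(2 * pen, p)
  vc <- tryCatch(solve(Hfinal), error = function(e) matrix(NA_real_, p, p))
  dimnames(vc) <- list(colnames(X), colnames(X))
  if (warn && separation)
    warning("complete separation detected; coefficients stabilized by ridge penalty",
            call. = FALSE)
  if (warn && !converged)
    warning("IRLS did not reach gradient tolerance ", tol, " in ", max_iter,
            " iterations", call. = FALSE)

  structure(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                 vcov = vc,
                 loglik = sum(y * eta - log1pexp(eta)),
                 converged = converged,
                 separation = separation,
                 iterations = iter,
                 predictor_names = colnames(x),
                 positive = positive,
                 ridge = ridge,
                 n = length(y)),
            class = "logistic_model")
}

#' @export
coef.logistic_model <- function(object, ...) object$coefficients

#' @export
vcov.logistic_model <- function(object, ...) object$vcov

#' @export
logLik.logistic_model <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' @export
print.logistic_model <- function(x, digits = 4, ...) {
  cat("Logistic regression (IRLS",
      if (x$ridge > 0) sprintf(", ridge = %g", x$ridge) else "", ")\n", sep = "")
  print(round(x$coefficients, digits))
  cat(sprintf("log-likelihood: %.4f on %d videos; converged: %s%s\n",
              x$loglik, x$n, x$converged,
              if (x$separation) "; separation flagged" else ""))
  invisible(x)
}

#' Predicted probability of the positive (GTS) class
#'
#' Applies the inverse-logit link `1 / (1 + exp(-(b0 + sum(b_j x_j))))` to
#' new predictor values.
#'
#' @param object A `"logistic_model"`.
#' @param newdata data.frame or matrix containing the model's predictors by
#'   name.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.logistic_model <- function(object, newdata, ...) {
  nms <- object$predictor_names
  if (length(nms)) {
    if (is.null(colnames(newdata)) || !all(nms %in% colnames(newdata)))
      stop("newdata is missing predictor(s): ",
           paste(setdiff(nms, colnames(newdata)), collapse = ", "), call. = FALSE)
    X <- as.matrix(as.data.frame(newdata)[, nms, drop = FALSE])
    if (any(!is.finite(X))) stop("non-finite predictor value", call. = FALSE)
    eta <- object$coefficients[1L] + drop(X %*% object$coefficients[-1L])
  } else {
    n <- if (is.null(dim(newdata))) length(newdata) else nrow(newdata)
    eta <- rep(object$coefficients[1L], n)
  }
  stats::plogis(eta)
}
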