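#' Hyperparameter grids for the elastic net
#'
#' Inclusive arithmetic sequences; the endpoint is included only when it lies
#' on the grid (within 1e-9). The defaults reproduce the study grid: alpha
#' from 0.1 to 1 in steps of 0.05 (19 values) and lambda from 0.001 to 0.15
#' in steps of 0.009 (17 values, ending at 0.145 because 0.15 is off-grid).
#'
#' @param start,end,by sequence bounds and increment (`by > 0`,
#'   `start <= end`).
#' @return numeric vector.
#' @export
build_grid <- function(start, end, by) {
  stopifnot(by > 0, start <= end)
  n <- floor((end - start) / by + 1e-9)
  g <- start + by * (0:n)
  if (length(g) == 0) stop("empty grid")
  g
}

#' @rdname build_grid
#' @return `default_grids()`: list with `alpha` and `lambda` vectors.
#' @export
default_grids <- function() {
  list(alpha = build_grid(0.1, 1, 0.05),
       lambda = build_grid(0.001, 0.15, 0.009))
}

#' Elastic-net penalty
#'
#' `lambda * (alpha * sum|b| + (1-alpha)/2 * sum b^2)`, intercept excluded.
#'
#' @param beta coefficient vector (no intercept).
#' @param alpha L1/L2 mixing in \[0, 1\].
#' @param lambda penalty strength.
#' @return scalar penalty.
#' @export
penalty <- function(beta, alpha, lambda) {
  stopifnot(all(is.finite(beta)), alpha >= 0, alpha <= 1, lambda >= 0)
  lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

#' Fit a single elastic-net logistic regression
#'
#' Minimizes the mean binomial negative log-likelihood plus
#' [penalty()] by iteratively reweighted least squares with coordinate
#' descent (the standard algorithm for this model). Predictors are used as
#' given (no internal standardization); the intercept is unpenalized. The
#' recorded objective trace is non-increasing.
#'
#' @param X numeric matrix (n x p).
#' @param y binary response (0/1), both classes present.
#' @param alpha,lambda elastic-net hyperparameters.
#' @param beta_init,intercept_init warm-start values.
#' @param tol convergence tolerance on the coefficient change.
#' @param maxit maximum IRLS iterations.
#' @param screen use strong-rule screening with KKT verification (exact;
#'   worthwhile for wide problems).
#' @return a `tibrad_enet` list: `beta` (named), `intercept`, `objective`,
#'   `trace`, `iterations`, `converged`, `alpha`, `lambda`.
#' @export
fit_elastic_net <- function(X, y, alpha, lambda,
                            beta_init = NULL, intercept_init = NULL,
                            tol = 1e-7, maxit = 100, screen = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)),
            alpha >= 0, alpha <= 1, lambda >= 0)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  p <- ncol(X)
  if (is.null(beta_init)) beta_init <- rep(0, p)
  if (is.null(intercept_init)) intercept_init <- qlogis(mean(y))
  fit <- enet_fit_cpp(X, y, alpha, lambda, as.numeric(beta_init),
                      intercept_init, tol, as.integer(maxit),
                      if (screen) lambda else -1)
  if (!fit$converged) {
    stop(sprintf(paste0("elastic-net solver did not converge in %d IRLS ",
                        "iterations (last objective %.6g); increase maxit"),
                 maxit, fit$objective))
  }
  structure(list(beta = setNames(as.numeric(fit$beta),
                                 colnames(X) %||% paste0("x", seq_len(p))),
                 intercept = fit$intercept, objective = fit$objective,
                 trace = fit$trace, iterations = fit$iterations,
                 converged = fit$converged, alpha = alpha, lambda = lambda),
            class = "tibrad_enet")
}

#' Linear predictor / probability for an elastic-net fit
#' @param object a `tibrad_enet`.
#' @param newdata matrix with the same columns as the training matrix.
#' @param type `"response"` (probability) or `"link"`.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.tibrad_enet <- function(object, newdata, type = c("response", "link"),
                                ...) {
  type <- match.arg(type)
  eta <- as.numeric(as.matrix(newdata) %*% object$beta + object$intercept)
  if (type == "response") plogis(eta) else eta
}

#' Full elastic-net objective (for diagnostics and tests)
#' @param X,y data.
#' @param beta,intercept coefficients.
#' @param alpha,lambda hyperparameters.
#' @return scalar objective value.
#' @export
enet_objective <- function(X, y, beta, intercept, alpha, lambda) {
  eta <- as.numeric(as.matrix(X) %*% beta + intercept)
  nll <- mean(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta)
  nll + penalty(beta, alpha, lambda)
}
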