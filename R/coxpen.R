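# Penalized Cox comparators: ridge, adaptive lasso, and elastic net fitted by
# proximal gradient descent on the Breslow partial likelihood.
#
# The objective is the negative log partial likelihood plus, per feature j,
#   ridge:          lambda * beta_j^2
#   adaptive lasso: lambda * w_j * |beta_j|       (w_j = 1/|ridge beta_j|)
#   elastic net:    lambda * (alpha |beta_j| + (1 - alpha) beta_j^2 / 2)
# The quadratic penalty parts join the smooth term; the l1 part is handled by
# weighted soft thresholding, with a backtracking line search on the smooth
# majorizer.

#' Penalty specification for penalized Cox regression
#'
#' @param kind `"ridge"`, `"adaptive_lasso"`, or `"elastic_net"`.
#' @param alpha elastic-net mixing parameter in (0, 1].
#' @param weights per-feature positive l1 weights (adaptive lasso); default 1.
#' @return object of class `penalty_spec`.
#' @export
penalty_spec <- function(kind = c("ridge", "adaptive_lasso", "elastic_net"),
                         alpha = 0.5, weights = NULL) {
  kind <- match.arg(kind)
  if (kind == "elastic_net" && (alpha <= 0 || alpha > 1))
    stop_config("'alpha' must lie in (0, 1]")
  if (!is.null(weights) && any(weights <= 0))
    stop_config("'weights' must be positive")
  structure(list(kind = kind, alpha = alpha, weights = weights),
            class = "penalty_spec")
}

# Decompose a penalty at level lambda into its smooth quadratic coefficient
# c2 (penalty contribution c2 * beta^2) and per-feature l1 levels.
penalty_parts <- function(penalty, lambda, p) {
  w <- penalty$weights %||% rep(1, p)
  switch(penalty$kind,
         ridge = list(c2 = lambda, l1 = rep(0, p)),
         adaptive_lasso = list(c2 = 0, l1 = lambda * w),
         elastic_net = list(c2 = lambda * (1 - penalty$alpha) / 2,
                            l1 = lambda * penalty$alpha * w))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit a penalized Cox model by proximal gradient descent
#'
#' @param X numeric covariate matrix (samples x features).
#' @param surv aligned survival table with at least one event.
#' @param penalty a [penalty_spec()].
#' @param lambda nonnegative penalty level.
#' @param beta_init optional warm-start coefficients.
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_iter iteration cap.
#' @return object of class `coxpen_fit`: `beta` (named), `lambda`, `penalty`,
#'   `converged`, `n_iter`, `objective`.
#' @export
fit_penalized_cox <- function(X, surv, penalty, lambda, beta_init = NULL,
                              tol = 1e-6, max_iter = 10000) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(surv)) stop_data("X and survival table misaligned")
  if (lambda < 0) stop_config("'lambda' must be nonnegative")
  if (sum(surv$event) < 1) stop_data("no events; partial likelihood undefined")
  p <- ncol(X)
  parts <- penalty_parts(penalty, lambda, p)
  smooth_f <- function(beta) {
    neg_log_partial_likelihood(as.numeric(X %*% beta), surv) +
      parts$c2 * sum(beta^2)
  }
  smooth_g <- function(beta) {
    as.numeric(crossprod(X, neg_log_partial_likelihood_grad(
      as.numeric(X %*% beta), surv))) + 2 * parts$c2 * beta
  }
  beta <- beta_init %||% rep(0, p)
  f_cur <- smooth_f(beta)
  step <- 1
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    g <- smooth_g(beta)
    repeat {
      cand <- soft_threshold(beta - step * g, step * parts$l1)
      d <- cand - beta
      f_new <- smooth_f(cand)
      # backtracking on the quadratic majorizer of the smooth part
      if (is.finite(f_new) &&
          f_new <= f_cur + sum(g * d) + sum(d^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-14) break
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    f_cur <- f_new
    step <- min(step * 1.25, 1e6) # cautiously re-expand the step size
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("proximal gradient did not converge in ", max_iter,
            " iterations (last max coefficient change ",
            format(delta, digits = 3), ")")
  names(beta) <- colnames(X) %||% paste0("x", seq_len(p))
  structure(list(beta = beta, lambda = lambda, penalty = penalty,
                 converged = converged, n_iter = it,
                 objective = f_cur + sum(parts$l1 * abs(beta))),
            class = "coxpen_fit")
}

#' First-order (KKT) optimality violation of a penalized fit
#'
#' For zero coefficients the smooth gradient must lie inside the l1
#' subdifferential (`|g_j| <= l1_j`); for nonzero coefficients
#' `g_j + l1_j * sign(beta_j)` must vanish. Returns the largest violation.
#'
#' @param fit a [fit_penalized_cox()] result.
#' @param X,surv the data the fit was produced from.
#' @return maximum KKT violation (0 at an exact optimum).
#' @export
kkt_violation <- function(fit, X, surv) {
  X <- as.matrix(X)
  p <- ncol(X)
  parts <- penalty_parts(fit$penalty, fit$lambda, p)
  g <- as.numeric(crossprod(X, neg_log_partial_likelihood_grad(
    as.numeric(X %*% fit$beta), surv))) + 2 * parts$c2 * fit$beta
  viol <- ifelse(fit$beta == 0,
                 pmax(abs(g) - parts$l1, 0),
                 abs(g + parts$l1 * sign(fit$beta)))
  max(viol)
}

#' Adaptive-lasso weights from a ridge fit
#'
#' `w_j = 1 / |beta_j0|` with the ridge estimate as initial coefficient;
#' near-zero initial estimates are capped at `1e8` (effectively excluding
#' the feature).
#'
#' @param ridge_fit a converged ridge [fit_penalized_cox()].
#' @return named numeric weight vector.
#' @export
adaptive_weights <- function(ridge_fit) {
  b <- abs(ridge_fit$beta)
  w <- ifelse(b < 1e-8, 1e8, 1 / b)
  stats::setNames(pmin(w, 1e8), names(ridge_fit$beta))
}

default_lambda_grid <- function(X, surv, penalty, n_lambda = 50, decades = 4) {
  p <- ncol(X)
  g0 <- as.numeric(crossprod(X, neg_log_partial_likelihood_grad(
    rep(0, nrow(X)), surv)))
  w <- penalty$weights %||% rep(1, p)
  denom <- switch(penalty$kind, ridge = 1, adaptive_lasso = w,
                  elastic_net = penalty$alpha * w)
  lambda_max <- max(abs(g0) / denom)
  exp(seq(log(lambda_max), log(lambda_max) - decades * log(10),
          length.out = n_lambda))
}

#' Cross-validated lambda path for penalized Cox regression
#'
#' Folds are built by survival-time-stratified partitioning. The per-lambda
#' criterion is the Verweij-van Houwelingen cross-validated partial-likelihood
#' deviance: for each fold, `-2 * (loglik_full(beta_-f) -
#' loglik_without_fold(beta_-f))`, summed over folds. Fits are warm-started
#' down the (descending) grid. Folds without events are skipped with a
#' warning. Only the minimum-lambda model is selected.
#'
#' @inheritParams fit_penalized_cox
#' @param n_folds number of cross-validation folds (default 9).
#' @param lambda_grid optional descending grid; by default 50 log-spaced
#'   values spanning four decades below the smallest all-zero-solution
#'   lambda.
#' @param seed seed for the fold assignment.
#' @return object of class `lambda_path`: `lambda_grid`, `cv_deviance`,
#'   `cv_se`, `lambda_min`, `folds_used`.
#' @export
cv_lambda_path <- function(X, surv, penalty, n_folds = 9, lambda_grid = NULL,
                           seed = 1) {
  X <- as.matrix(X)
  if (n_folds < 2) stop_config("'n_folds' must be >= 2")
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(X, surv, penalty)
  if (is.unsorted(rev(lambda_grid), strictly = TRUE) && length(lambda_grid) > 1)
    stop_config("'lambda_grid' must be strictly descending")
  folds <- stratified_partition(surv, k = n_folds, seed = seed)$partition
  usable <- logical(n_folds)
  contrib <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (f in seq_len(n_folds)) {
    out <- folds != f
    if (sum(surv$event[out]) < 1 || sum(surv$event[!out]) < 1) {
      warning("fold ", f, " has no events on one side of the split; skipped")
      next
    }
    usable[f] <- TRUE
    beta <- rep(0, ncol(X))
    for (li in seq_along(lambda_grid)) {
      fit <- fit_penalized_cox(X[out, , drop = FALSE], surv[out, ], penalty,
                               lambda_grid[li], beta_init = beta)
      beta <- fit$beta
      ll_full <- -neg_log_partial_likelihood(as.numeric(X %*% beta), surv)
      ll_out <- -neg_log_partial_likelihood(
        as.numeric(X[out, , drop = FALSE] %*% beta), surv[out, ])
      contrib[f, li] <- -2 * (ll_full - ll_out)
    }
  }
  if (!any(usable)) stop("every cross-validation fold was skipped")
  cv_dev <- colSums(contrib[usable, , drop = FALSE])
  cv_se <- apply(contrib[usable, , drop = FALSE], 2, stats::sd) *
    sqrt(sum(usable))
  structure(list(lambda_grid = lambda_grid, cv_deviance = cv_dev,
                 cv_se = cv_se,
                 lambda_min = lambda_grid[which.min(cv_dev)],
                 folds_used = sum(usable)),
            class = "lambda_path")
}

#' Rank features by absolute coefficient amplitude
#'
#' @param fit a [fit_penalized_cox()] result.
#' @return character vector of feature names, `|beta|` descending, ties
#'   broken lexicographically. Warns when every coefficient is zero.
#' @export
rank_by_coefficient <- function(fit) {
  b <- fit$beta
  if (all(b == 0)) warning("all coefficients are zero; ranking is degenerate")
  names(b)[order(-abs(b), names(b))]
}
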