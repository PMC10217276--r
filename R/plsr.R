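#' Partial least squares regression (PLS1, NIPALS)
#'
#' Sequential NIPALS extraction with deflation for a single response:
#' weights \eqn{w = X^T y / \|X^T y\|}, scores \eqn{t = Xw}, loadings
#' \eqn{p = X^T t / t^T t}, response loading \eqn{q = y^T t / t^T t},
#' then deflation of X and y. Regression coefficients are
#' \eqn{B = W (P^T W)^{-1} q}; with as many components as the feature rank
#' this collapses to ordinary least squares. Training RMSE is non-increasing
#' in the number of components.
#'
#' @param X Feature matrix (e.g. latent-variable scores).
#' @param y Numeric response (\eqn{^\circ}Brix).
#' @param ncomp Number of components, at most
#'   \code{min(nrow(X) - 1, ncol(X))}.
#' @return An object of class \code{plsr_model} with coefficients, means and
#'   the per-component weight/score/loading vectors.
#' @export
plsr_fit <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), ncomp >= 1)
  if (ncomp > min(nrow(X) - 1L, ncol(X))) {
    stop(sprintf("ncomp = %d exceeds the rank limit min(n - 1, p) = %d",
                 ncomp, min(nrow(X) - 1L, ncol(X))))
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  W <- P <- matrix(0, ncol(X), ncomp)
  Tm <- matrix(0, nrow(X), ncomp)
  q <- numeric(ncomp)
  a <- 0L
  for (comp in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # residual response orthogonal to X (e.g. constant y)
    w <- w / nw
    t_sc <- drop(E %*% w)
    tt <- sum(t_sc^2)
    p <- drop(crossprod(E, t_sc)) / tt
    qa <- sum(f * t_sc) / tt
    E <- E - tcrossprod(t_sc, p)
    f <- f - qa * t_sc
    a <- comp
    W[, comp] <- w; P[, comp] <- p; Tm[, comp] <- t_sc; q[comp] <- qa
  }
  coef <- if (a == 0L) numeric(ncol(X)) else {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
  }
  structure(list(ncomp = a, x_mean = x_mean, y_mean = y_mean,
                 weights = W[, seq_len(max(a, 1L)), drop = FALSE],
                 loadings = P[, seq_len(max(a, 1L)), drop = FALSE],
                 scores = Tm[, seq_len(max(a, 1L)), drop = FALSE],
                 y_loadings = q[seq_len(max(a, 1L))],
                 coefficients = coef),
            class = "plsr_model")
}

#' Predict from a fitted PLS1 model
#'
#' \eqn{\hat{y} = (X - \bar{X}) B + \bar{y}}.
#'
#' @param model A \code{\link{plsr_fit}} model.
#' @param X Feature matrix with the fitted width.
#' @return Predicted response vector.
#' @export
plsr_predict <- function(model, X) {
  stopifnot(inherits(model, "plsr_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_mean)) {
    stop(sprintf("feature width %d does not match the fitted width %d",
                 ncol(X), length(model$x_mean)))
  }
  drop(sweep(X, 2, model$x_mean) %*% model$coefficients) + model$y_mean
}
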