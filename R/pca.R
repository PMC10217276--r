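#' Principal component analysis of pretreated spectra
#'
#' Mean-centres the wavelength columns (no variance scaling -- the
#' contribution rates operate on covariance eigenvalues) and decomposes the
#' sample covariance. Loading signs are fixed so each column's
#' largest-magnitude element is positive, making repeated fits identical.
#'
#' @param x A \code{\link{spectrum_set}} or numeric matrix with >= 2 rows.
#' @return An object of class \code{pca_model} with fields
#'   \code{mean_spectrum}, \code{loadings} (wavelength x LV),
#'   \code{eigenvalues} (descending, n-1 convention), \code{contribution}
#'   (per-LV variance share \eqn{\varphi_i}), \code{cumulative}
#'   (\eqn{\Phi_k}), \code{m} (total spectral dimensionality) and
#'   \code{wavelengths}.
#' @export
fit_pca <- function(x) {
  mat <- if (inherits(x, "spectrum_set")) x$absorbance else as.matrix(x)
  wl <- if (inherits(x, "spectrum_set")) x$wavelengths else seq_len(ncol(mat))
  if (nrow(mat) < 2) stop("PCA needs at least 2 samples")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  load <- pc$rotation
  ev <- pc$sdev^2
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  rates <- contribution_rates(ev)
  structure(list(mean_spectrum = pc$center, loadings = load,
                 eigenvalues = ev, contribution = rates$phi,
                 cumulative = rates$cumulative, m = ncol(mat),
                 wavelengths = wl),
            class = "pca_model")
}

#' Per-component contribution rates and cumulative rates
#'
#' \eqn{\varphi_i = \lambda_i / \sum_j \lambda_j} is the variance share of
#' the i-th latent variable and \eqn{\Phi_k = \sum_{i \le k} \varphi_i} its
#' running total, the quantity the component-selection threshold is applied
#' to.
#'
#' @param eigenvalues Non-negative eigenvalues, not all zero.
#' @return \code{list(phi =, cumulative =)}.
#' @export
contribution_rates <- function(eigenvalues) {
  stopifnot(is.numeric(eigenvalues), all(eigenvalues >= 0))
  tot <- sum(eigenvalues)
  if (tot == 0) stop("all eigenvalues are zero")
  phi <- eigenvalues / tot
  list(phi = phi, cumulative = cumsum(phi))
}

#' Select the number of latent variables by cumulative contribution
#'
#' Smallest \eqn{k} with \eqn{\Phi_k \ge} threshold. The conventional
#' threshold is 0.95; 0.99 retains nearly all spectral variance.
#'
#' @param cumulative Non-decreasing cumulative contribution rates.
#' @param threshold Proportion in (0, 1].
#' @return Integer \eqn{k}.
#' @export
select_k <- function(cumulative, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  if (threshold > cumulative[length(cumulative)] + 1e-12) {
    stop(sprintf("threshold %g exceeds the attainable cumulative rate %g",
                 threshold, cumulative[length(cumulative)]))
  }
  which(cumulative >= threshold - 1e-12)[1]
}

#' Project spectra onto fitted principal components
#'
#' Scores of the first \eqn{k} latent variables:
#' \eqn{(X - \bar{x}) L_{1..k}}. The spectra must share the fitted
#' wavelength grid.
#'
#' @param x A \code{\link{spectrum_set}} or matrix.
#' @param model A \code{\link{fit_pca}} model.
#' @param k Number of components (default: all).
#' @return Score matrix (samples x k).
#' @export
pca_transform <- function(x, model, k = ncol(model$loadings)) {
  stopifnot(inherits(model, "pca_model"), k >= 0,
            k <= ncol(model$loadings))
  mat <- if (inherits(x, "spectrum_set")) x$absorbance else as.matrix(x)
  if (inherits(x, "spectrum_set") &&
      (length(x$wavelengths) != length(model$wavelengths) ||
       any(x$wavelengths != model$wavelengths))) {
    stop("wavelength grid does not match the fitted PCA model")
  }
  if (ncol(mat) != model$m) stop("wavelength grid does not match the fitted PCA model")
  ctr <- sweep(mat, 2, model$mean_spectrum)
  ctr %*% model$loadings[, seq_len(k), drop = FALSE]
}
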