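#' Spectral pretreatment configuration
#'
#' Selects one of the six pretreatment operators compared in this package
#' (or \code{"none"} for raw spectra) and its Savitzky--Golay parameters.
#'
#' @param method One of \code{"snv"}, \code{"vn"}, \code{"sg"}, \code{"fd"},
#'   \code{"sd"}, \code{"sd-sg"}, \code{"none"}.
#' @param sg_window Odd window length in points (default 7).
#' @param sg_polyorder Polynomial order, less than \code{sg_window} (default 3).
#' @param sg_first If \code{TRUE}, \code{"sd-sg"} smooths before
#'   differentiating instead of the default derivative-then-smooth order
#'   (sensitivity toggle).
#' @return An object of class \code{pretreatment_config}.
#' @export
pretreatment_config <- function(method = "sd-sg", sg_window = 7L,
                                sg_polyorder = 3L, sg_first = FALSE) {
  methods <- c("snv", "vn", "sg", "fd", "sd", "sd-sg", "none")
  if (!is.character(method) || length(method) != 1L || !method %in% methods) {
    stop(sprintf("unknown pretreatment method '%s'; valid methods: %s",
                 paste(method, collapse = ","), paste(methods, collapse = ", ")))
  }
  check_sg_params(sg_window, sg_polyorder)
  structure(list(method = method, sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 sg_first = isTRUE(sg_first)),
            class = "pretreatment_config")
}

check_sg_params <- function(window, polyorder) {
  if (window %% 2 == 0 || window < 3) stop("sg_window must be odd and >= 3")
  if (polyorder >= window) stop("sg_polyorder must be smaller than sg_window")
  invisible(TRUE)
}

#' Standard normal variate transform
#'
#' Centres and scales each spectrum to zero mean and unit (n-1) standard
#' deviation, removing per-sample offset and multiplicative scatter.
#'
#' @param x A \code{\link{spectrum_set}}.
#' @return A \code{spectrum_set} whose rows have mean 0 and sd 1.
#' @export
snv <- function(x) {
  stopifnot(inherits(x, "spectrum_set"))
  s <- apply(x$absorbance, 1, stats::sd)
  if (any(s == 0)) {
    stop(sprintf("degenerate (constant) spectrum for sample '%s'",
                 x$sample_ids[which(s == 0)[1]]))
  }
  set_absorbance(x, (x$absorbance - rowMeans(x$absorbance)) / s)
}

#' Vector normalisation
#'
#' Divides each spectrum by its Euclidean norm, removing per-sample scale.
#'
#' @param x A \code{\link{spectrum_set}}.
#' @return A \code{spectrum_set} whose rows have unit Euclidean norm.
#' @export
vector_normalize <- function(x) {
  stopifnot(inherits(x, "spectrum_set"))
  nrm <- sqrt(rowSums(x$absorbance^2))
  if (any(nrm == 0)) {
    stop(sprintf("all-zero spectrum for sample '%s'",
                 x$sample_ids[which(nrm == 0)[1]]))
  }
  set_absorbance(x, x$absorbance / nrm)
}

#' Savitzky--Golay smoothing weight matrix
#'
#' Row i holds the weights producing the smoothed value at point i of an
#' n-point spectrum. Interior points use the centred window; within half a
#' window of either end the window is truncated one-sided, so the output
#' keeps the input length. When a truncated window has no more points than
#' the polynomial order the fit is exact and the point passes through.
#'
#' @noRd
sg_weight_matrix <- function(n, window, polyorder) {
  half <- (window - 1L) %/% 2L
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    idx <- lo:hi
    p <- min(polyorder, length(idx) - 1L)
    # design in local coordinates; smoothed value = value of the LS
    # polynomial at offset 0, i.e. e1' (A'A)^-1 A' applied to the window
    A <- outer(idx - i, 0:p, `^`)
    W[i, idx] <- solve(crossprod(A), t(A))[1, ]
  }
  W
}

#' Savitzky--Golay smoothing
#'
#' Local least-squares polynomial smoothing with fixed convolution weights at
#' interior points and truncated one-sided polynomial fits at the edges, so
#' the output grid keeps all 81 points. Exactly reproduces polynomial rows of
#' degree up to \code{polyorder}.
#'
#' @param x A \code{\link{spectrum_set}}.
#' @param window Odd window length in points.
#' @param polyorder Polynomial order, \code{< window}.
#' @return A smoothed \code{spectrum_set}.
#' @export
sg_smooth <- function(x, window = 7L, polyorder = 3L) {
  stopifnot(inherits(x, "spectrum_set"))
  check_sg_params(window, polyorder)
  n <- length(x$wavelengths)
  if (window > n) stop("sg_window exceeds the wavelength grid length")
  W <- sg_weight_matrix(n, as.integer(window), as.integer(polyorder))
  set_absorbance(x, x$absorbance %*% t(W))
}

#' Spectral derivative by finite differences
#'
#' First order: central difference \eqn{(x_{i+1}-x_{i-1})/(2\Delta\lambda)};
#' second order: \eqn{(x_{i+1}-2x_i+x_{i-1})/\Delta\lambda^2}; one-sided
#' differences at the two endpoints keep the output length. Units are AU per
#' nm (order 1) or per nm\eqn{^2} (order 2). First derivatives annihilate
#' constant rows; second derivatives annihilate affine rows.
#'
#' @param x A \code{\link{spectrum_set}} on a uniform grid of >= 3 points.
#' @param order Derivative order, 1 or 2.
#' @return A \code{spectrum_set} of derivative spectra.
#' @export
spectral_derivative <- function(x, order = 1L) {
  stopifnot(inherits(x, "spectrum_set"), order %in% c(1L, 2L))
  wl <- x$wavelengths
  n <- length(wl)
  if (n < 3) stop("derivative needs a grid of at least 3 points")
  d <- diff(wl)
  if (max(abs(d - d[1])) > 1e-8 * d[1]) stop("derivative requires a uniform wavelength grid")
  h <- d[1]
  A <- x$absorbance
  out <- A
  ii <- 2:(n - 1)
  if (order == 1L) {
    out[, ii] <- (A[, ii + 1L] - A[, ii - 1L]) / (2 * h)
    out[, 1L] <- (A[, 2L] - A[, 1L]) / h
    out[, n] <- (A[, n] - A[, n - 1L]) / h
  } else {
    out[, ii] <- (A[, ii + 1L] - 2 * A[, ii] + A[, ii - 1L]) / h^2
    out[, 1L] <- (A[, 3L] - 2 * A[, 2L] + A[, 1L]) / h^2
    out[, n] <- (A[, n] - 2 * A[, n - 1L] + A[, n - 2L]) / h^2
  }
  set_absorbance(x, out)
}

#' Second derivative followed by Savitzky--Golay smoothing
#'
#' The combination pretreatment: the second derivative removes baseline
#' offset and linear drift, and the subsequent smoothing suppresses the noise
#' the differentiation amplified. The reverse order is available via
#' \code{sg_first}.
#'
#' @param x A \code{\link{spectrum_set}}.
#' @param window,polyorder Savitzky--Golay parameters.
#' @param sg_first Smooth before differentiating (default \code{FALSE}).
#' @return A pretreated \code{spectrum_set}.
#' @export
sd_sg <- function(x, window = 7L, polyorder = 3L, sg_first = FALSE) {
  if (isTRUE(sg_first)) {
    spectral_derivative(sg_smooth(x, window, polyorder), order = 2L)
  } else {
    sg_smooth(spectral_derivative(x, order = 2L), window, polyorder)
  }
}

#' Apply a configured pretreatment
#'
#' Dispatches to the operator selected in a
#' \code{\link{pretreatment_config}}; \code{"none"} is the identity.
#'
#' @param x A \code{\link{spectrum_set}}.
#' @param config A \code{\link{pretreatment_config}} (or a method name).
#' @return The pretreated \code{spectrum_set}.
#' @export
pretreat <- function(x, config = pretreatment_config()) {
  if (is.character(config)) config <- pretreatment_config(config)
  stopifnot(inherits(config, "pretreatment_config"))
  methods <- c("snv", "vn", "sg", "fd", "sd", "sd-sg", "none")
  if (!config$method %in% methods) {
    stop(sprintf("unknown pretreatment method '%s'; valid methods: %s",
                 config$method, paste(methods, collapse = ", ")))
  }
  switch(config$method,
         snv = snv(x),
         vn = vector_normalize(x),
         sg = sg_smooth(x, config$sg_window, config$sg_polyorder),
         fd = spectral_derivative(x, 1L),
         sd = spectral_derivative(x, 2L),
         `sd-sg` = sd_sg(x, config$sg_window, config$sg_polyorder,
                         config$sg_first),
         none = x)
}
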