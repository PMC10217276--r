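#' Empirical hidden-layer size
#'
#' The classical rule \eqn{h = round(\sqrt{m + n}) + a} for a three-layer
#' network with \eqn{m} inputs and \eqn{n} outputs, where \eqn{a} is an
#' adjustable constant between 1 and 10. With 35 latent-variable inputs and
#' 3 grade outputs the admissible range is 7--16; \eqn{a = 8} gives the
#' 14-neuron hidden layer used for classification.
#'
#' @param m,n Input and output neuron counts (>= 1).
#' @param a Adjustable constant in \eqn{[1, 10]}.
#' @return Integer hidden-layer size.
#' @export
hidden_size <- function(m, n, a) {
  stopifnot(m >= 1, n >= 1)
  if (a < 1 || a > 10) stop("adjustable constant a must lie in [1, 10]")
  as.integer(round(sqrt(m + n)) + a)
}

#' Dynamic learning-rate decay schedule
#'
#' One of four nonlinear decay strategies, or a fixed rate. All decays start
#' at (or near) \eqn{\eta_0} and are non-increasing over \eqn{t \in [0, T]}:
#' \describe{
#'   \item{fixed}{\eqn{\eta_0}}
#'   \item{exponential}{\eqn{\eta_0 (1 - t/T)^p} (\eqn{p>1} concave,
#'     \eqn{0<p<1} convex)}
#'   \item{cosine}{\eqn{0.5\,\eta_0 (1 + \cos(t\pi/T))}}
#'   \item{gaussian}{\eqn{\eta_0 \exp(-t^2/(2\gamma^2))}}
#'   \item{sigmoid}{\eqn{\eta_0 / (1 + e^{\gamma (t - T/2)})}}
#' }
#'
#' @param kind Schedule name.
#' @param eta0 Initial learning rate, > 0.
#' @param T Total iteration count, >= 1.
#' @param p Exponent of the exponential decay (default 2).
#' @param gamma Attenuation rate of the gaussian/sigmoid decays; defaults
#'   \eqn{T/3} (gaussian) and \eqn{10/T} (sigmoid).
#' @return An object of class \code{lr_schedule}.
#' @export
lr_schedule <- function(kind = c("fixed", "exponential", "cosine", "gaussian",
                                 "sigmoid"),
                        eta0 = 0.001, T = 3000L, p = 2, gamma = NULL) {
  kind <- match.arg(kind)
  stopifnot(eta0 >= 0, T >= 1, p > 0)
  if (is.null(gamma)) gamma <- if (kind == "sigmoid") 10 / T else T / 3
  stopifnot(gamma > 0)
  structure(list(kind = kind, eta0 = eta0, T = as.integer(T), p = p,
                 gamma = gamma),
            class = "lr_schedule")
}

#' Learning rate at an iteration
#'
#' @param schedule An \code{\link{lr_schedule}}.
#' @param t Iteration in \eqn{[0, T]} (vectorised).
#' @return Learning rate(s).
#' @export
lr_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "lr_schedule"))
  if (any(t < 0 | t > schedule$T)) {
    stop(sprintf("iteration t must lie in [0, %d]", schedule$T))
  }
  with(schedule, switch(kind,
    fixed = rep_len(eta0, length(t)),
    exponential = eta0 * (1 - t / T)^p,
    cosine = 0.5 * eta0 * (1 + cos(t * pi / T)),
    gaussian = eta0 * exp(-t^2 / (2 * gamma^2)),
    sigmoid = eta0 / (1 + exp(gamma * (t - T / 2)))))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialise a three-layer back-propagation network
#'
#' Weights are drawn uniformly on \eqn{[-0.5, 0.5]}; thresholds (biases)
#' start at zero. Deterministic per seed.
#'
#' @param m,h,n Input, hidden and output neuron counts.
#' @param output_activation \code{"sigmoid"} for 3-grade classification
#'   (\eqn{n = 3}) or \code{"linear"} for \eqn{^\circ}Brix regression
#'   (\eqn{n = 1}).
#' @param seed Integer seed.
#' @return An object of class \code{bpnn_model}.
#' @export
init_bpnn <- function(m, h, n, output_activation = c("sigmoid", "linear"),
                      seed = 1L) {
  output_activation <- match.arg(output_activation)
  if (m < 1 || h < 1 || n < 1) stop("layer sizes must be positive")
  with_seed(seed, {
    structure(list(
      m = as.integer(m), h = as.integer(h), n = as.integer(n),
      hidden_weights = matrix(stats::runif(m * h, -0.5, 0.5), m, h),
      hidden_thresholds = numeric(h),
      output_weights = matrix(stats::runif(h * n, -0.5, 0.5), h, n),
      output_thresholds = numeric(n),
      output_activation = output_activation),
      class = "bpnn_model")
  })
}

#' Forward pass of a BPNN
#'
#' Hidden layer uses the logistic sigmoid; the output layer uses the model's
#' configured activation.
#'
#' @param model A \code{\link{init_bpnn}} model.
#' @param X Input matrix (samples x m) or vector of length m.
#' @return Output matrix (samples x n).
#' @export
bpnn_forward <- function(model, X) {
  stopifnot(inherits(model, "bpnn_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$m) {
    stop(sprintf("input width %d does not match m = %d", ncol(X), model$m))
  }
  H <- sigmoid(sweep(X %*% model$hidden_weights, 2, model$hidden_thresholds, `+`))
  Z <- sweep(H %*% model$output_weights, 2, model$output_thresholds, `+`)
  if (model$output_activation == "sigmoid") sigmoid(Z) else Z
}

#' Mean-squared-error loss of a BPNN on a batch
#' @noRd
bpnn_loss <- function(model, X, Y) {
  mean((bpnn_forward(model, X) - Y)^2)
}

#' Analytic gradients of the batch MSE loss
#'
#' Back-propagated gradients of \eqn{L = mean((\hat{Y} - Y)^2)} (mean over
#' all samples and output units) with respect to every weight and threshold.
#' Exposed so the analytic gradient can be audited against numerical
#' differentiation.
#'
#' @param model A \code{\link{init_bpnn}} model.
#' @param X Input matrix (samples x m).
#' @param Y Target matrix (samples x n): one-hot rows for classification,
#'   a column of responses for regression.
#' @return \code{list(hidden_weights, hidden_thresholds, output_weights,
#'   output_thresholds)} of gradient arrays matching the model's shapes.
#' @export
bpnn_gradients <- function(model, X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  H <- sigmoid(sweep(X %*% model$hidden_weights, 2, model$hidden_thresholds, `+`))
  Z <- sweep(H %*% model$output_weights, 2, model$output_thresholds, `+`)
  Yhat <- if (model$output_activation == "sigmoid") sigmoid(Z) else Z
  dL <- 2 * (Yhat - Y) / length(Y)
  D2 <- if (model$output_activation == "sigmoid") dL * Yhat * (1 - Yhat) else dL
  D1 <- (D2 %*% t(model$output_weights)) * H * (1 - H)
  list(hidden_weights = t(X) %*% D1,
       hidden_thresholds = colSums(D1),
       output_weights = t(H) %*% D2,
       output_thresholds = colSums(D2))
}

#' Train a BPNN by full-batch gradient descent
#'
#' Plain gradient descent (no momentum, no minibatching); epoch \eqn{t} uses
#' the learning rate \code{lr_at(schedule, t)}. Inputs are expected to be
#' standardised by the caller. Targets are one-hot rows (classification,
#' MSE on sigmoid outputs) or a response column (regression, MSE on the
#' linear output).
#'
#' @param model A \code{\link{init_bpnn}} model.
#' @param X Feature matrix (samples x m).
#' @param Y Target matrix (samples x n).
#' @param schedule An \code{\link{lr_schedule}} with \code{T >= epochs}.
#' @param epochs Number of full-batch epochs.
#' @return \code{list(model, trace)} where \code{trace} is a data frame with
#'   per-epoch training \code{mse} and \code{lr}.
#' @export
train_gd <- function(model, X, Y, schedule = lr_schedule("fixed", T = epochs),
                     epochs = 1800L) {
  stopifnot(inherits(model, "bpnn_model"), inherits(schedule, "lr_schedule"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != model$m || ncol(Y) != model$n || nrow(X) != nrow(Y)) {
    stop("feature/target shapes do not match the network topology")
  }
  if (epochs > schedule$T) stop("epochs exceed the schedule's total iterations T")
  mse <- lr <- numeric(epochs)
  for (t in seq_len(epochs)) {
    eta <- lr_at(schedule, t)
    g <- bpnn_gradients(model, X, Y)
    model$hidden_weights <- model$hidden_weights - eta * g$hidden_weights
    model$hidden_thresholds <- model$hidden_thresholds - eta * g$hidden_thresholds
    model$output_weights <- model$output_weights - eta * g$output_weights
    model$output_thresholds <- model$output_thresholds - eta * g$output_thresholds
    loss <- bpnn_loss(model, X, Y)
    if (!is.finite(loss)) stop(sprintf("training diverged (NaN loss) at epoch %d", t))
    mse[t] <- loss
    lr[t] <- eta
  }
  list(model = model, trace = data.frame(epoch = seq_len(epochs), mse = mse, lr = lr))
}

#' Predict grades from a classification BPNN
#'
#' Argmax over the three sigmoid outputs; ties break toward the lower grade
#' index.
#'
#' @param model A classification \code{\link{init_bpnn}} model
#'   (sigmoid output).
#' @param X Feature matrix.
#' @return Integer grades.
#' @export
predict_grade <- function(model, X) {
  stopifnot(inherits(model, "bpnn_model"))
  if (model$output_activation != "sigmoid") {
    stop("predict_grade requires a classification (sigmoid-output) model")
  }
  out <- bpnn_forward(model, X)
  as.integer(apply(out, 1, which.max))
}

#' One-hot encode grades
#'
#' @param grade Integer grades.
#' @param levels Class levels (default 1:3).
#' @return Matrix with one indicator column per level.
#' @export
one_hot <- function(grade, levels = 1:3) {
  out <- matrix(0, length(grade), length(levels))
  out[cbind(seq_along(grade), match(grade, levels))] <- 1
  out
}
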