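#' Particle swarm configuration
#'
#' Parameters of the velocity/position update
#' \deqn{v_i \leftarrow \omega v_i + c_1 r_1 (pbest_i - x_i) + c_2 r_2 (gbest - x_i),
#'       \quad x_i \leftarrow x_i + v_i}
#' with per-dimension uniform random factors. The classification defaults
#' (\eqn{\omega = 0.2}, \eqn{c_1 = 1.4}, \eqn{c_2 = 2}) are the tuned values
#' for the grading task; the regression task uses \eqn{\omega = 0.7},
#' \eqn{c_1 = 1.9}, \eqn{c_2 = 1.7}.
#'
#' @param n_particles Swarm size N (>= 2).
#' @param omega Inertia weight in (0, 1].
#' @param c1,c2 Cognitive and social acceleration factors, > 0.
#' @param iterations Number of update steps.
#' @param bounds Symmetric position box half-width (positions live in
#'   \code{[-bounds, bounds]} per dimension).
#' @param vclamp Velocity clamp as a fraction of the box width.
#' @param seed Integer seed.
#' @return An object of class \code{swarm_config}.
#' @export
swarm_config <- function(n_particles = 30L, omega = 0.2, c1 = 1.4, c2 = 2,
                         iterations = 100L, bounds = 2, vclamp = 0.5,
                         seed = 1L) {
  stopifnot(n_particles >= 1, omega > 0, omega <= 1, c1 > 0, c2 > 0,
            iterations >= 0, is.finite(bounds), bounds > 0,
            vclamp > 0)
  structure(list(n_particles = as.integer(n_particles), omega = omega,
                 c1 = c1, c2 = c2, iterations = as.integer(iterations),
                 bounds = bounds, vclamp = vclamp, seed = as.integer(seed)),
            class = "swarm_config")
}

#' Initialise a particle swarm
#'
#' Positions uniform in the box, velocities uniform within the clamp;
#' optionally seeds particle 1 at a supplied position (used to warm-start
#' network optimisation from an initialised model). Fitness of every
#' particle is evaluated once to set personal and global bests.
#'
#' @param fitness Function position vector -> scalar (lower is better).
#' @param dim Search-space dimensionality.
#' @param config A \code{\link{swarm_config}}.
#' @param init_position Optional numeric vector placed as particle 1
#'   (clipped into the box).
#' @return An object of class \code{swarm}.
#' @export
init_swarm <- function(fitness, dim, config = swarm_config(),
                       init_position = NULL) {
  stopifnot(dim >= 1)
  vmax <- config$vclamp * 2 * config$bounds
  with_seed(config$seed, {
    X <- matrix(stats::runif(config$n_particles * dim, -config$bounds,
                             config$bounds),
                config$n_particles, dim)
    V <- matrix(stats::runif(config$n_particles * dim, -vmax, vmax),
                config$n_particles, dim)
    if (!is.null(init_position)) {
      stopifnot(length(init_position) == dim)
      X[1, ] <- pmin(pmax(init_position, -config$bounds), config$bounds)
      V[1, ] <- 0
    }
    fit <- eval_fitness(fitness, X)
    best <- which.min(fit)
    structure(list(positions = X, velocities = V,
                   pbest = X, pbest_fitness = fit,
                   gbest = X[best, ], gbest_fitness = fit[best],
                   k = 0L, dim = dim),
              class = "swarm")
  })
}

eval_fitness <- function(fitness, X) {
  fit <- vapply(seq_len(nrow(X)), function(i) fitness(X[i, ]), numeric(1))
  if (any(!is.finite(fit))) {
    stop(sprintf("fitness returned a non-finite value for particle %d",
                 which(!is.finite(fit))[1]))
  }
  fit
}

#' One particle-swarm update step
#'
#' Applies the velocity and position updates with per-dimension uniform
#' random factors, clamps velocities, clips positions into the box, and
#' updates personal/global bests by fitness comparison. The global best
#' fitness is non-increasing across steps. The caller manages RNG state
#' (\code{\link{pso_optimize}} runs the whole trajectory under one seed).
#'
#' @param swarm A \code{\link{init_swarm}} swarm.
#' @param fitness Function position vector -> scalar.
#' @param config A \code{\link{swarm_config}}.
#' @return The updated \code{swarm}.
#' @export
pso_step <- function(swarm, fitness, config) {
  stopifnot(inherits(swarm, "swarm"), inherits(config, "swarm_config"))
  N <- nrow(swarm$positions); d <- swarm$dim
  vmax <- config$vclamp * 2 * config$bounds
  r1 <- matrix(stats::runif(N * d), N, d)
  r2 <- matrix(stats::runif(N * d), N, d)
  V <- config$omega * swarm$velocities +
    config$c1 * r1 * (swarm$pbest - swarm$positions) +
    config$c2 * r2 * (matrix(swarm$gbest, N, d, byrow = TRUE) - swarm$positions)
  V <- pmin(pmax(V, -vmax), vmax)
  X <- pmin(pmax(swarm$positions + V, -config$bounds), config$bounds)
  fit <- eval_fitness(fitness, X)
  improved <- fit < swarm$pbest_fitness
  swarm$pbest[improved, ] <- X[improved, , drop = FALSE]
  swarm$pbest_fitness[improved] <- fit[improved]
  best <- which.min(swarm$pbest_fitness)
  swarm$gbest <- swarm$pbest[best, ]
  swarm$gbest_fitness <- swarm$pbest_fitness[best]
  swarm$positions <- X
  swarm$velocities <- V
  swarm$k <- swarm$k + 1L
  swarm
}

#' Minimise a fitness function by particle swarm optimisation
#'
#' Runs \code{\link{pso_step}} for the configured number of iterations under
#' the config seed and returns the best position with the per-iteration
#' global-best fitness trace (non-increasing by construction). With zero
#' iterations the best of the initial population is returned.
#'
#' @param fitness Function position vector -> scalar (lower is better).
#' @param dim Search-space dimensionality.
#' @param config A \code{\link{swarm_config}}.
#' @param init_position Optional warm-start position for particle 1.
#' @return \code{list(position, fitness, trace)}; \code{trace} holds the
#'   global-best fitness after each iteration (index 1 = initial
#'   population).
#' @export
pso_optimize <- function(fitness, dim, config = swarm_config(),
                         init_position = NULL) {
  swarm <- init_swarm(fitness, dim, config, init_position)
  trace <- numeric(config$iterations + 1L)
  trace[1] <- swarm$gbest_fitness
  with_seed(config$seed + 1L, {
    for (it in seq_len(config$iterations)) {
      swarm <- pso_step(swarm, fitness, config)
      trace[it + 1L] <- swarm$gbest_fitness
    }
  })
  list(position = swarm$gbest, fitness = swarm$gbest_fitness, trace = trace)
}

#' Flatten a BPNN's weights and thresholds into a particle vector
#'
#' @param model A \code{\link{init_bpnn}} model.
#' @return Numeric vector (the PSO search space).
#' @export
bpnn_flatten <- function(model) {
  c(model$hidden_weights, model$hidden_thresholds,
    model$output_weights, model$output_thresholds)
}

#' Rebuild a BPNN from a particle vector
#'
#' Inverse of \code{\link{bpnn_flatten}}; the round trip reproduces
#' identical forward outputs.
#'
#' @param theta Numeric vector of length \eqn{mh + h + hn + n}.
#' @param m,h,n Layer sizes.
#' @param output_activation Output activation of the rebuilt model.
#' @return A \code{bpnn_model}.
#' @export
bpnn_unflatten <- function(theta, m, h, n,
                           output_activation = c("sigmoid", "linear")) {
  output_activation <- match.arg(output_activation)
  stopifnot(length(theta) == m * h + h + h * n + n)
  i <- 0L
  take <- function(k) {
    out <- theta[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
  structure(list(m = as.integer(m), h = as.integer(h), n = as.integer(n),
                 hidden_weights = matrix(take(m * h), m, h),
                 hidden_thresholds = take(h),
                 output_weights = matrix(take(h * n), h, n),
                 output_thresholds = take(n),
                 output_activation = output_activation),
            class = "bpnn_model")
}

#' Train a BPNN by PSO with gradient-descent refinement
#'
#' Each particle encodes the full set of network weights and thresholds;
#' fitness is the training-set MSE of the decoded network (training error
#' only -- using test-set accuracy as fitness would leak). Particle 1 is
#' warm-started at a seed-initialised network so the swarm never starts
#' worse than plain initialisation. After the swarm converges, the best
#' network is fine-tuned by \code{\link{train_gd}} under the supplied decay
#' schedule.
#'
#' @param X Feature matrix (samples x m), standardised by the caller.
#' @param Y Target matrix as in \code{\link{train_gd}}.
#' @param topology \code{list(m, h, n, output_activation)}.
#' @param config A \code{\link{swarm_config}}.
#' @param schedule An \code{\link{lr_schedule}} for the refinement phase.
#' @param gd_epochs Refinement epochs (0 skips gradient descent: pso-only).
#' @param seed Seed for the warm-start network initialisation.
#' @param init_model Optional \code{bpnn_model} used as the warm-start
#'   particle instead of a fresh seed-initialised network.
#' @return \code{list(model, pso_trace, gd_trace)}.
#' @export
pso_train_bpnn <- function(X, Y, topology, config = swarm_config(),
                           schedule = lr_schedule("gaussian", eta0 = 0.001,
                                                  T = 1800L),
                           gd_epochs = 1800L, seed = 1L, init_model = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  m <- topology$m; h <- topology$h; n <- topology$n
  act <- topology$output_activation %||% "sigmoid"
  if (ncol(X) != m || ncol(Y) != n) {
    stop("feature/target widths do not match the requested topology")
  }
  fitness <- function(theta) {
    bpnn_loss(bpnn_unflatten(theta, m, h, n, act), X, Y)
  }
  init <- bpnn_flatten(init_model %||% init_bpnn(m, h, n, act, seed = seed))
  dim <- length(init)
  opt <- pso_optimize(fitness, dim, config, init_position = init)
  model <- bpnn_unflatten(opt$position, m, h, n, act)
  gd_trace <- NULL
  if (gd_epochs > 0) {
    fit <- train_gd(model, X, Y, schedule, epochs = gd_epochs)
    # keep the refined model only if refinement did not overshoot
    if (bpnn_loss(fit$model, X, Y) <= opt$fitness) model <- fit$model
    gd_trace <- fit$trace
  }
  list(model = model, pso_trace = opt$trace, gd_trace = gd_trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
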