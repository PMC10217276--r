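test_that("hidden_size follows the square-root empirical rule", {
  expect_identical(hidden_size(2, 2, 1), 3L)
  expect_identical(hidden_size(35, 3, 8), 14L)  # the grading topology
  admissible <- sapply(1:10, function(a) hidden_size(35, 3, a))
  expect_identical(admissible, 7:16)
  expect_error(hidden_size(35, 3, 11), "\\[1, 10\\]")
  expect_error(hidden_size(35, 3, 0), "\\[1, 10\\]")
})

test_that("learning-rate schedules match their closed forms", {
  T <- 1000
  for (kind in c("fixed", "exponential", "cosine", "gaussian", "sigmoid")) {
    s <- lr_schedule(kind, eta0 = 0.4, T = T, p = 1)
    expect_equal(lr_at(s, 0), if (kind == "sigmoid")
      0.4 / (1 + exp(-s$gamma * T / 2)) else 0.4, tolerance = 1e-12)
  }
  expect_equal(lr_at(lr_schedule("cosine", eta0 = 0.4, T = T), T), 0)
  expect_equal(lr_at(lr_schedule("cosine", eta0 = 0.4, T = T), T / 2), 0.2)
  expect_equal(lr_at(lr_schedule("exponential", eta0 = 0.4, T = T, p = 1),
                     T / 2), 0.2)
  expect_equal(lr_at(lr_schedule("gaussian", eta0 = 0.4, T = T), 0), 0.4)
  expect_error(lr_at(lr_schedule("fixed", T = 10), 11), "\\[0, 10\\]")
})

test_that("every decay schedule is non-increasing on [0, T]", {
  T <- 500
  grid <- 0:T
  for (kind in c("fixed", "exponential", "cosine", "gaussian", "sigmoid")) {
    eta <- lr_at(lr_schedule(kind, eta0 = 0.1, T = T), grid)
    expect_true(all(diff(eta) <= 1e-15), info = kind)
  }
})

test_that("initialisation is seeded, shaped, and bounded", {
  a <- init_bpnn(2, 3, 1, "linear", seed = 7)
  b <- init_bpnn(2, 3, 1, "linear", seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, init_bpnn(2, 3, 1, "linear", seed = 8)))
  expect_identical(dim(a$hidden_weights), c(2L, 3L))
  expect_identical(dim(a$output_weights), c(3L, 1L))
  expect_true(all(abs(a$hidden_weights) <= 0.5))
  expect_identical(a$hidden_thresholds, numeric(3))
  expect_error(init_bpnn(0, 3, 1), "positive")
})

test_that("forward pass honours activations and determinism", {
  m <- init_bpnn(2, 3, 3, "sigmoid", seed = 1)
  m$hidden_weights[] <- 0; m$output_weights[] <- 0
  expect_equal(bpnn_forward(m, rbind(c(1, 2), c(-4, 0))),
               matrix(0.5, 2, 3), ignore_attr = TRUE)
  r <- init_bpnn(2, 3, 1, "linear", seed = 1)
  r$hidden_weights[] <- 0; r$output_weights[] <- 0
  expect_equal(bpnn_forward(r, c(5, -5)), matrix(0, 1, 1), ignore_attr = TRUE)
  x <- rmat(4, 2, seed = 2)
  expect_identical(bpnn_forward(m, x), bpnn_forward(m, x))
  expect_error(bpnn_forward(m, matrix(1, 2, 3)), "width 3.*m = 2")
})

test_that("analytic gradients match central finite differences", {
  numeric_grad <- function(model, X, Y, field, eps = 1e-6) {
    g <- model[[field]]
    for (i in seq_along(g)) {
      up <- model; up[[field]][i] <- up[[field]][i] + eps
      dn <- model; dn[[field]][i] <- dn[[field]][i] - eps
      g[i] <- (visbrix:::bpnn_loss(up, X, Y) -
                 visbrix:::bpnn_loss(dn, X, Y)) / (2 * eps)
    }
    g
  }
  fields <- c("hidden_weights", "hidden_thresholds",
              "output_weights", "output_thresholds")
  for (s in 1:6) {
    act <- if (s %% 2) "sigmoid" else "linear"
    model <- init_bpnn(3, 4, 2, act, seed = s)
    X <- rmat(5, 3, seed = s + 100)
    Y <- if (act == "sigmoid") one_hot(sample(1:2, 5, TRUE), 1:2) else
      rmat(5, 2, seed = s + 200)
    g <- bpnn_gradients(model, X, Y)
    for (f in fields) {
      ng <- numeric_grad(model, X, Y, f)
      expect_equal(as.numeric(g[[f]]), as.numeric(ng), tolerance = 1e-6,
                   info = paste(act, f))
    }
  }
})

test_that("gradient descent solves a separable toy and respects eta0 = 0", {
  toy <- separable_toy()
  Y <- one_hot(toy$grade, 1:2)
  m0 <- init_bpnn(2, 4, 2, "sigmoid", seed = 3)
  fit <- train_gd(m0, toy$X, Y, lr_schedule("fixed", eta0 = 0.5, T = 2000),
                  epochs = 2000)
  pred <- apply(bpnn_forward(fit$model, toy$X), 1, which.max)
  expect_identical(as.integer(pred), as.integer(toy$grade))
  expect_lt(tail(fit$trace$mse, 1), fit$trace$mse[1])
  # trace bookkeeping
  expect_identical(nrow(fit$trace), 2000L)
  expect_equal(fit$trace$lr, rep(0.5, 2000))
  frozen <- train_gd(m0, toy$X, Y, lr_schedule("fixed", eta0 = 0, T = 10),
                     epochs = 10)
  expect_identical(frozen$model$hidden_weights, m0$hidden_weights)
  expect_identical(frozen$model$output_weights, m0$output_weights)
})

test_that("training MSE decays along the schedule it reports", {
  toy <- separable_toy(n_per = 6, seed = 9)
  sched <- lr_schedule("gaussian", eta0 = 0.3, T = 300)
  fit <- train_gd(init_bpnn(2, 3, 2, "sigmoid", seed = 1), toy$X,
                  one_hot(toy$grade, 1:2), sched, epochs = 300)
  expect_equal(fit$trace$lr, lr_at(sched, 1:300), tolerance = 1e-12)
})

test_that("grade prediction is argmax with low-index tie-breaking", {
  m <- init_bpnn(3, 2, 3, "sigmoid", seed = 1)
  fake <- m
  # craft outputs through a zero-weight network with chosen thresholds
  fake$hidden_weights[] <- 0; fake$output_weights[] <- 0
  fake$output_thresholds <- stats::qlogis(c(0.9, 0.3, 0.1))
  expect_identical(predict_grade(fake, rbind(c(0, 0, 0))), 1L)
  fake$output_thresholds <- stats::qlogis(c(0.5, 0.5, 0.1))
  expect_identical(predict_grade(fake, rbind(c(0, 0, 0))), 1L)
  # batch equals per-row
  X <- rmat(6, 3, seed = 4)
  batch <- predict_grade(m, X)
  rows <- vapply(1:6, function(i) predict_grade(m, X[i, , drop = FALSE]),
                 integer(1))
  expect_identical(batch, rows)
  reg <- init_bpnn(3, 2, 1, "linear", seed = 1)
  expect_error(predict_grade(reg, X), "classification")
})
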