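test_that("classification report counts, averages, and validates", {
  r <- classification_report(c(1, 1, 2, 3), c(1, 1, 2, 2))
  expect_equal(r$accuracy, 75)
  expect_equal(sum(r$confusion), 4)
  expect_equal(r$accuracy, 100 * sum(diag(r$confusion)) / sum(r$confusion))
  # 29 of 33 correct prints as 87.88 at two decimals
  truth <- rep(c(1, 2, 3), times = c(13, 14, 6))
  pred <- truth
  pred[c(1, 14, 15, 28)] <- c(2, 1, 3, 2)
  r2 <- classification_report(truth, pred)
  expect_equal(round(r2$accuracy, 2), 87.88)
  perfect <- classification_report(truth, truth)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$macro_recall, 100)
  expect_equal(perfect$macro_f1, 1.0)
  expect_error(classification_report(integer(0), integer(0)), "empty")
})

test_that("macro averaging differs from accuracy under imbalance", {
  truth <- rep(c(1, 2, 3), times = c(2, 10, 2))
  pred <- c(2, 2, rep(2, 10), 2, 3)
  r <- classification_report(truth, pred)
  expect_false(isTRUE(all.equal(r$macro_recall, r$accuracy)))
  # F1 of a never-predicted class is 0
  expect_equal(unname(r$confusion[1, 1]), 0)
})

test_that("one-vs-rest AUC handles separation, ties, and transforms", {
  truth <- rep(c(1, 2, 3), times = c(4, 4, 4))
  sep <- one_hot(truth) + matrix(runif(36, 0, 0.01), 12, 3)
  expect_equal(unname(roc_auc(truth, sep)), rep(1, 3))
  flat <- matrix(0.5, 12, 3)
  expect_equal(unname(roc_auc(truth, flat)), rep(0.5, 3))
  set.seed(4)
  sc <- matrix(runif(36), 12, 3)
  expect_equal(roc_auc(truth, exp(3 * sc)), roc_auc(truth, sc))
  expect_error(roc_auc(rep(1, 5), matrix(runif(15), 5, 3)), "single-class")
})

test_that("AUC agrees with pROC and random scores centre on 0.5", {
  set.seed(9)
  truth <- sample(1:3, 40, replace = TRUE)
  sc <- matrix(runif(120), 40, 3)
  ours <- roc_auc(truth, sc)
  for (g in 1:3) {
    ref <- suppressMessages(pROC::auc(pROC::roc(truth == g, sc[, g],
                                                direction = "<", quiet = TRUE)))
    expect_equal(unname(ours[g]), as.numeric(ref), tolerance = 1e-10)
  }
  set.seed(10)
  mean_auc <- mean(replicate(100, {
    roc_auc(sample(rep(1:3, length.out = 200)),
            matrix(runif(600), 200, 3))[1]
  }))
  expect_lt(abs(mean_auc - 0.5), 0.05)
})

test_that("pearson r covers the sign and orthogonal cases", {
  y <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_r(y, 2 * y + 1), 1)
  expect_equal(pearson_r(y, -y), -1)
  expect_equal(pearson_r(c(1, 2, 1, 2), c(1, 1, 2, 2)), 0)
  expect_error(pearson_r(c(1, 1), c(1, 2)), "zero variance")
})

test_that("rmse matches hand arithmetic and bias", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 2), c(2, 4)), sqrt(2.5))
  y <- rnorm(10)
  expect_equal(rmse(y, y + 0.3), 0.3, tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "length mismatch")
})

test_that("rmse and pearson agree with textbook formulas on random vectors", {
  for (s in 1:50) {
    set.seed(s)
    y <- rnorm(20); yh <- rnorm(20)
    expect_equal(rmse(y, yh), sqrt(sum((yh - y)^2) / 20), tolerance = 1e-10)
    r_text <- sum((y - mean(y)) * (yh - mean(yh))) /
      sqrt(sum((y - mean(y))^2) * sum((yh - mean(yh))^2))
    expect_equal(pearson_r(y, yh), r_text, tolerance = 1e-10)
  }
})

test_that("leave-one-out RMSECV reproduces closed forms", {
  X <- matrix(0, 3, 1)
  fit_mean <- function(X, y) mean(y)
  pred_mean <- function(m, X) rep(m, nrow(X))
  expect_equal(loo_rmsecv(X, c(1, 2, 3), fit_mean, pred_mean), sqrt(1.5))
  # OLS on noise-free linear data cross-validates to zero
  set.seed(2)
  Xl <- matrix(rnorm(30), 15, 2)
  yl <- 1 + drop(Xl %*% c(2, -1))
  fit_ols <- function(X, y) lm.fit(cbind(1, X), y)$coefficients
  pred_ols <- function(b, X) drop(cbind(1, X) %*% b)
  expect_lt(loo_rmsecv(Xl, yl, fit_ols, pred_ols), 1e-9)
  # a memorising 1-NN still errs on held-out points
  fit_nn <- function(X, y) list(X = X, y = y)
  pred_nn <- function(m, X) {
    apply(X, 1, function(r) m$y[which.min(colSums((t(m$X) - r)^2))])
  }
  set.seed(3)
  Xn <- matrix(rnorm(20), 10, 2)
  expect_gt(loo_rmsecv(Xn, rnorm(10), fit_nn, pred_nn), 0)
  # k-fold fallback covers every sample once
  expect_gt(loo_rmsecv(Xn, rnorm(10), fit_mean, pred_mean, folds = 3), 0)
  bad_fit <- function(X, y) stop("boom")
  expect_error(loo_rmsecv(Xn, rnorm(10), bad_fit, pred_mean), "fold 1")
})

test_that("grade statistics reproduce the textbook identities", {
  g <- grade_statistics(c(1, 2, 3), rep(1L, 3))
  expect_equal(g$mean, 2)
  expect_equal(g$variance, 1)
  expect_equal(g$se_mean, 0.5774, tolerance = 1e-4)
  expect_equal(g$mad, 0.6667, tolerance = 1e-4)
  expect_equal(g$cv, 0.5)
  set.seed(5)
  ssc <- runif(30, 8, 18)
  grade <- assign_grade(ssc)
  tab <- grade_statistics(ssc, grade)
  expect_true(all(tab$min <= tab$mean & tab$mean <= tab$max))
  expect_equal(tab$se_mean, sqrt(tab$variance) / sqrt(tab$n), tolerance = 1e-12)
  expect_equal(tab$cv, sqrt(tab$variance) / tab$mean, tolerance = 1e-12)
  expect_error(grade_statistics(numeric(0), integer(0)), NA)
})
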