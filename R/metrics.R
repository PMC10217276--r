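#' Multiclass classification report
#'
#' Confusion matrix (rows = true grade, columns = predicted), accuracy in
#' percent, and macro-averaged recall (percent) and F1 score. Macro
#' averaging runs over the grades present in the truth; the F1 of a grade
#' never predicted is 0.
#'
#' @param truth,predicted Integer grades in \code{1:3}, equal length.
#' @return \code{list(confusion, accuracy, macro_recall, macro_f1)}.
#' @export
classification_report <- function(truth, predicted) {
  if (length(truth) == 0) stop("empty input")
  stopifnot(length(truth) == length(predicted),
            all(truth %in% 1:3), all(predicted %in% 1:3))
  cm <- table(factor(truth, levels = 1:3), factor(predicted, levels = 1:3))
  cm <- unclass(cm)
  present <- which(rowSums(cm) > 0)
  recall <- diag(cm)[present] / rowSums(cm)[present]
  prec_den <- colSums(cm)[present]
  precision <- ifelse(prec_den > 0, diag(cm)[present] / prec_den, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(confusion = cm,
       accuracy = 100 * sum(diag(cm)) / sum(cm),
       macro_recall = 100 * mean(recall),
       macro_f1 = mean(f1))
}

#' One-vs-rest ROC AUC per grade
#'
#' AUC from the midrank (Mann--Whitney) statistic, equivalent to trapezoidal
#' integration of the ROC curve with tied scores placed on the diagonal.
#' Invariant to strictly monotone transforms of the scores.
#'
#' @param truth Integer grades.
#' @param scores Matrix of continuous class scores (samples x grades), e.g.
#'   the network's sigmoid outputs; columns follow the grade levels.
#' @param levels Grade levels matching the score columns (default 1:3).
#' @return Named numeric vector of per-grade AUCs in \eqn{[0, 1]}.
#' @export
roc_auc <- function(truth, scores, levels = 1:3) {
  scores <- as.matrix(scores)
  stopifnot(length(truth) == nrow(scores), ncol(scores) == length(levels))
  vapply(seq_along(levels), function(j) {
    pos <- truth == levels[j]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) {
      stop(sprintf("AUC undefined for grade %s: single-class truth", levels[j]))
    }
    r <- rank(scores[, j])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1), USE.NAMES = FALSE) -> auc
  names(auc) <- paste0("grade", levels)
  auc
}

#' Pearson correlation between measured and predicted values
#'
#' @param y,yhat Numeric vectors of length >= 2 with nonzero variance.
#' @return Pearson product-moment correlation.
#' @export
pearson_r <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    stop("correlation undefined: zero variance")
  }
  stats::cor(y, yhat)
}

#' Root mean squared error
#'
#' \eqn{\sqrt{\sum (\hat{y}_i - y_i)^2 / n}}; reported as RMSEC on the
#' calibration (training) set and RMSEP on the prediction (testing) set.
#'
#' @param y,yhat Numeric vectors of equal length.
#' @return RMSE in the units of \code{y}.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch between y and yhat")
  sqrt(mean((yhat - y)^2))
}

#' Cross-validated RMSE (leave-one-out by default)
#'
#' Refits the supplied model once per fold, predicting each held-out block;
#' leave-one-out when \code{folds} is \code{NULL}, or k-fold (contiguous
#' blocks) as a cheaper alternative for expensive models.
#'
#' @param X Feature matrix.
#' @param y Numeric response.
#' @param fit Function \code{(X, y) -> model}.
#' @param predict Function \code{(model, X) -> yhat}.
#' @param folds Optional fold count; \code{NULL} for leave-one-out.
#' @return RMSECV over the held-out predictions.
#' @export
loo_rmsecv <- function(X, y, fit, predict, folds = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3, length(y) == n)
  assign_fold <- if (is.null(folds)) seq_len(n) else sort(rep_len(seq_len(folds), n))
  pred <- numeric(n)
  for (f in unique(assign_fold)) {
    hold <- which(assign_fold == f)
    model <- tryCatch(fit(X[-hold, , drop = FALSE], y[-hold]),
                      error = function(e) {
                        stop(sprintf("model fit failed on fold %s: %s",
                                     f, conditionMessage(e)))
                      })
    pred[hold] <- predict(model, X[hold, , drop = FALSE])
  }
  rmse(y, pred)
}

#' Descriptive statistics per grade
#'
#' For each grade: n, minimum, maximum, mean, sample (n-1) variance,
#' standard error of the mean (\eqn{\sqrt{var}/\sqrt{n}}), mean absolute
#' deviation about the mean, and coefficient of variation
#' (\eqn{\sqrt{var}/mean}). All in \eqn{^\circ}Brix except n and CV.
#'
#' @param ssc Numeric SSC values.
#' @param grade Integer grades per value.
#' @return Data frame, one row per grade.
#' @export
grade_statistics <- function(ssc, grade) {
  stopifnot(length(ssc) == length(grade))
  levels <- sort(unique(grade))
  rows <- lapply(levels, function(g) {
    x <- ssc[grade == g]
    if (length(x) == 0) stop(sprintf("grade %s is empty", g))
    v <- stats::var(x)
    data.frame(grade = g, n = length(x), min = min(x), max = max(x),
               mean = mean(x), variance = v,
               se_mean = sqrt(v) / sqrt(length(x)),
               mad = mean(abs(x - mean(x))),
               cv = sqrt(v) / mean(x))
  })
  do.call(rbind, rows)
}
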