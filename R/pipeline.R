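#' Pipeline configuration
#'
#' Bundles every stage's parameters for the qualitative (3-grade
#' classification) and quantitative (\eqn{^\circ}Brix regression) studies.
#' Exactly one data source is used: a \code{\link{spectrum_set}} or a
#' \code{\link{synthetic_config}} (the default generator when neither is
#' given). All stage seeds are derived from the single master \code{seed},
#' so a run is fully reproduced by its resolved configuration.
#'
#' Stage defaults follow the tuned values of the grading study where those
#' exist: classification learning rate 0.001 with the Gaussian decay
#' schedule, hidden size from \code{\link{hidden_size}} with \eqn{a = 8},
#' swarm \eqn{\omega = 0.2, c_1 = 1.4, c_2 = 2}; regression hidden size 10
#' and swarm \eqn{\omega = 0.7, c_1 = 1.9, c_2 = 1.7} with 400 iterations.
#'
#' @param data Optional \code{\link{spectrum_set}}.
#' @param synthetic Optional \code{\link{synthetic_config}}.
#' @param pretreatment A \code{\link{pretreatment_config}}.
#' @param seed Master integer seed.
#' @param ... Stage overrides, merged recursively into the defaults:
#'   \code{pca} (threshold, k_override), \code{smote} (multipliers,
#'   k_neighbors), \code{split} (fraction, order), \code{bpnn} (hidden, a,
#'   eta0, epochs, schedule), \code{pso} (enabled, n_particles, omega, c1,
#'   c2, iterations, bounds, vclamp), \code{regression} (hidden, eta0,
#'   epochs, omega, c1, c2, iterations), \code{plsr} (n_components),
#'   \code{outdir}.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(data = NULL, synthetic = NULL,
                            pretreatment = pretreatment_config("sd-sg"),
                            seed = 1L, ...) {
  if (!is.null(data) && !is.null(synthetic)) {
    stop("supply exactly one data source: data or synthetic")
  }
  if (is.null(data) && is.null(synthetic)) synthetic <- synthetic_config()
  if (!is.null(data)) stopifnot(inherits(data, "spectrum_set"))
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  defaults <- list(
    pca = list(threshold = 0.95, k_override = NULL),
    smote = list(multipliers = c(3L, 1L, 4L), k_neighbors = 5L),
    split = list(fraction = 0.2, order = NULL),
    bpnn = list(hidden = NULL, a = 8L, eta0 = 0.001, epochs = 1800L,
                schedule = list(kind = "gaussian", p = 2, gamma = NULL)),
    pso = list(enabled = TRUE, n_particles = 30L, omega = 0.2, c1 = 1.4,
               c2 = 2, iterations = 100L, bounds = 2, vclamp = 0.5),
    regression = list(hidden = 10L, eta0 = 0.05, epochs = 2000L,
                      omega = 0.7, c1 = 1.9, c2 = 1.7, iterations = 400L),
    plsr = list(n_components = 5L),
    rmsecv_folds = NULL,
    outdir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown pipeline config block(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over)
  cfg$data <- data
  cfg$synthetic <- synthetic
  cfg$pretreatment <- pretreatment
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

resolve_data <- function(config) {
  if (!is.null(config$data)) config$data else generate_spectra(config$synthetic)
}

std_fit <- function(X) {
  s <- apply(X, 2, stats::sd)
  s[s < 1e-12] <- 1
  list(mean = colMeans(X), sd = s)
}

std_apply <- function(X, std) sweep(sweep(X, 2, std$mean), 2, std$sd, `/`)

pick_k <- function(model, config) {
  if (!is.null(config$pca$k_override)) {
    min(as.integer(config$pca$k_override), ncol(model$loadings))
  } else {
    select_k(model$cumulative, config$pca$threshold)
  }
}

class_schedule <- function(config, epochs) {
  lr_schedule(config$bpnn$schedule$kind, eta0 = config$bpnn$eta0, T = epochs,
              p = config$bpnn$schedule$p %||% 2,
              gamma = config$bpnn$schedule$gamma)
}

#' Run the qualitative (3-grade classification) study
#'
#' Executes pretreat, PCA feature extraction, SMOTE augmentation,
#' stratified 8:2 split, training-side standardisation, BPNN training
#' (PSO-optimised with gradient-descent refinement by default, plain
#' decayed gradient descent when \code{pso$enabled} is \code{FALSE}) and
#' test-set evaluation.
#'
#' Two split protocols are supported via \code{split$order}:
#' \code{"augment_first"} (default here) augments the full score table and
#' then splits 8:2, while \code{"split_first"} splits the raw samples first
#' and fits PCA, SMOTE and standardisation on the training side only (no
#' test-set leakage).
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return A report list: confusion matrix, accuracy, macro recall/F1,
#'   per-grade AUC (NA where a grade is absent from the test truth),
#'   train-set accuracy, selected \code{k} and hidden size, traces, and the
#'   resolved configuration.
#' @export
run_qualitative <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- resolve_data(config)
  if (is.null(data$grade) || any(is.na(data$grade))) {
    stop("stage qualitative: every sample needs a grade")
  }
  order <- config$split$order %||% "augment_first"
  pre <- stage("pretreatment", pretreat(data, config$pretreatment))
  if (order == "augment_first") {
    pca <- stage("pca", fit_pca(pre))
    k <- pick_k(pca, config)
    scores <- pca_transform(pre, pca, k)
    aug <- stage("smote", smote(scores, data$grade, config$smote$multipliers,
                                config$smote$k_neighbors,
                                seed = config$seed + 2L))
    idx <- stage("split", stratified_split_idx(aug$grades, config$split$fraction,
                                               seed = config$seed + 1L))
    x_tr <- aug$features[idx$train, , drop = FALSE]
    x_te <- aug$features[idx$test, , drop = FALSE]
    g_tr <- aug$grades[idx$train]
    g_te <- aug$grades[idx$test]
  } else if (order == "split_first") {
    idx <- stage("split", stratified_split_idx(data$grade, config$split$fraction,
                                               seed = config$seed + 1L))
    pca <- stage("pca", fit_pca(pre[idx$train]))
    k <- pick_k(pca, config)
    aug <- stage("smote", smote(pca_transform(pre[idx$train], pca, k),
                                data$grade[idx$train],
                                config$smote$multipliers,
                                config$smote$k_neighbors,
                                seed = config$seed + 2L))
    x_tr <- aug$features
    g_tr <- aug$grades
    x_te <- pca_transform(pre[idx$test], pca, k)
    g_te <- data$grade[idx$test]
  } else {
    stop("stage split: order must be 'augment_first' or 'split_first'")
  }
  std <- std_fit(x_tr)
  x_tr <- std_apply(x_tr, std)
  x_te <- std_apply(x_te, std)
  h <- config$bpnn$hidden %||% hidden_size(k, 3L, config$bpnn$a)
  schedule <- class_schedule(config, config$bpnn$epochs)
  Y <- one_hot(g_tr)
  if (isTRUE(config$pso$enabled)) {
    fit <- stage("pso", pso_train_bpnn(
      x_tr, Y, list(m = k, h = h, n = 3L, output_activation = "sigmoid"),
      swarm_config(config$pso$n_particles, config$pso$omega, config$pso$c1,
                   config$pso$c2, config$pso$iterations, config$pso$bounds,
                   config$pso$vclamp, seed = config$seed + 4L),
      schedule, gd_epochs = config$bpnn$epochs, seed = config$seed + 3L))
    model <- fit$model
    traces <- list(pso = fit$pso_trace, gd = fit$gd_trace)
  } else {
    fit <- stage("bpnn", train_gd(
      init_bpnn(k, h, 3L, "sigmoid", seed = config$seed + 3L),
      x_tr, Y, schedule, epochs = config$bpnn$epochs))
    model <- fit$model
    traces <- list(gd = fit$trace)
  }
  pred <- predict_grade(model, x_te)
  rep <- classification_report(g_te, pred)
  auc <- tryCatch(roc_auc(g_te, bpnn_forward(model, x_te)),
                  error = function(e) {
                    a <- rep(NA_real_, 3)
                    names(a) <- paste0("grade", 1:3)
                    a
                  })
  report <- c(rep, list(
    auc = auc,
    train_accuracy = classification_report(g_tr, predict_grade(model, x_tr))$accuracy,
    k = k, hidden = h, n_train = nrow(x_tr), n_test = length(g_te),
    traces = traces, config = config))
  write_artifacts(report, config, "qualitative")
  report
}

#' Run the quantitative (\eqn{^\circ}Brix regression) study
#'
#' Splits the raw labelled samples 8:2 (stratified by grade), fits the
#' pretreatment + PCA features on the training side, augments the training
#' scores by SMOTE (SSC interpolated along with the features), standardises
#' features and response on the training side, and trains a single-output
#' linear-head BPNN -- PSO-optimised with decayed gradient-descent
#' refinement by default. Calibration metrics (\eqn{r_{cal}}, RMSEC) are
#' reported on the original (non-synthetic) training samples and prediction
#' metrics (\eqn{r_{pre}}, RMSEP) on the held-out test samples.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param model One of \code{"pso-bpnn"} (default), \code{"bpnn"} (plain
#'   decayed gradient descent) or \code{"plsr"} (the linear baseline on the
#'   same latent-variable scores).
#' @return A report list with r_cal, rmsec, r_pre, rmsep, optional rmsecv,
#'   predictions, the selected k, traces and the resolved configuration.
#' @export
run_quantitative <- function(config = pipeline_config(),
                             model = c("pso-bpnn", "bpnn", "plsr")) {
  stopifnot(inherits(config, "pipeline_config"))
  model <- match.arg(model)
  data <- resolve_data(config)
  if (is.null(data$ssc) || any(is.na(data$ssc))) {
    stop("stage quantitative: every sample needs an SSC label")
  }
  order <- config$split$order %||% "split_first"
  if (order != "split_first") {
    stop("stage split: the quantitative study supports split_first only")
  }
  idx <- stage("split", stratified_split_idx(data$grade, config$split$fraction,
                                             seed = config$seed + 1L))
  pre <- stage("pretreatment", pretreat(data, config$pretreatment))
  pca <- stage("pca", fit_pca(pre[idx$train]))
  k <- pick_k(pca, config)
  s_tr <- pca_transform(pre[idx$train], pca, k)
  s_te <- pca_transform(pre[idx$test], pca, k)
  aug <- stage("smote", smote(s_tr, data$grade[idx$train],
                              config$smote$multipliers,
                              config$smote$k_neighbors,
                              seed = config$seed + 2L,
                              extra = data$ssc[idx$train]))
  std <- std_fit(aug$features)
  x_aug <- std_apply(aug$features, std)
  x_cal <- std_apply(s_tr, std)
  x_te <- std_apply(s_te, std)
  y_mean <- mean(aug$extra); y_sd <- stats::sd(aug$extra)
  y_aug <- (aug$extra - y_mean) / y_sd
  reg <- config$regression
  traces <- NULL
  fit_one <- function(X, y) {
    if (model == "plsr") {
      plsr_fit(X, y, min(config$plsr$n_components, min(nrow(X) - 1L, ncol(X))))
    } else if (model == "bpnn") {
      train_gd(init_bpnn(ncol(X), reg$hidden, 1L, "linear",
                         seed = config$seed + 3L),
               X, matrix(y), lr_schedule(config$bpnn$schedule$kind,
                                         eta0 = reg$eta0, T = reg$epochs,
                                         gamma = config$bpnn$schedule$gamma),
               epochs = reg$epochs)
    } else {
      pso_train_bpnn(X, matrix(y),
                     list(m = ncol(X), h = reg$hidden, n = 1L,
                          output_activation = "linear"),
                     swarm_config(config$pso$n_particles, reg$omega, reg$c1,
                                  reg$c2, reg$iterations, config$pso$bounds,
                                  config$pso$vclamp, seed = config$seed + 4L),
                     lr_schedule(config$bpnn$schedule$kind, eta0 = reg$eta0,
                                 T = reg$epochs,
                                 gamma = config$bpnn$schedule$gamma),
                     gd_epochs = reg$epochs, seed = config$seed + 3L)
    }
  }
  predict_one <- function(fit, X) {
    if (model == "plsr") plsr_predict(fit, X)
    else drop(bpnn_forward(fit$model, X)) * y_sd + y_mean
  }
  fit <- stage(model, fit_one(x_aug, if (model == "plsr") aug$extra else y_aug))
  if (model == "pso-bpnn") traces <- list(pso = fit$pso_trace, gd = fit$gd_trace)
  if (model == "bpnn") traces <- list(gd = fit$trace)
  pred_cal <- predict_one(fit, x_cal)
  pred_te <- predict_one(fit, x_te)
  y_cal <- data$ssc[idx$train]
  y_te <- data$ssc[idx$test]
  rmsecv <- NULL
  if (!is.null(config$rmsecv_folds)) {
    rmsecv <- loo_rmsecv(x_aug, if (model == "plsr") aug$extra else y_aug,
                         fit_one, function(m, X) {
                           p <- if (model == "plsr") plsr_predict(m, X) else
                             drop(bpnn_forward(m$model, X))
                           p
                         },
                         folds = if (config$rmsecv_folds > 0) config$rmsecv_folds)
    if (model != "plsr") rmsecv <- rmsecv * y_sd
  }
  report <- list(model = model,
                 r_cal = pearson_r(y_cal, pred_cal),
                 rmsec = rmse(y_cal, pred_cal),
                 r_pre = pearson_r(y_te, pred_te),
                 rmsep = rmse(y_te, pred_te),
                 rmsecv = rmsecv,
                 predictions = data.frame(sample_id = data$sample_ids[idx$test],
                                          ssc = y_te, predicted = pred_te),
                 k = k, n_train = nrow(x_aug), n_test = length(y_te),
                 traces = traces, config = config)
  write_artifacts(report, config, "quantitative")
  report
}

#' Compare pretreatment methods on the qualitative task
#'
#' Runs the qualitative pipeline once per pretreatment operator (the six
#' methods plus raw spectra) with shared data and seeds, and returns a
#' comparison table of selected latent variables, hidden size and test-set
#' classification metrics.
#'
#' @param config A \code{\link{pipeline_config}}; its \code{pretreatment}
#'   block supplies the Savitzky--Golay parameters.
#' @param methods Methods to compare (default all six plus \code{"none"}).
#' @return A data frame with one row per method and attribute
#'   \code{"reports"} holding the full per-method reports.
#' @export
compare_pretreatments <- function(config = pipeline_config(),
                                  methods = c("snv", "vn", "sg", "fd", "sd",
                                              "sd-sg", "none")) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- resolve_data(config)
  reports <- lapply(methods, function(m) {
    cfg <- config
    cfg$data <- data
    cfg$synthetic <- NULL
    cfg$pretreatment <- pretreatment_config(m, config$pretreatment$sg_window,
                                            config$pretreatment$sg_polyorder,
                                            config$pretreatment$sg_first)
    cfg$outdir <- NULL
    run_qualitative(cfg)
  })
  names(reports) <- methods
  out <- data.frame(method = methods,
                    k = vapply(reports, `[[`, integer(1), "k"),
                    hidden = vapply(reports, function(r) as.integer(r$hidden),
                                    integer(1)),
                    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
                    macro_recall = vapply(reports, `[[`, numeric(1),
                                          "macro_recall"),
                    macro_f1 = vapply(reports, `[[`, numeric(1), "macro_f1"),
                    row.names = NULL)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(config$outdir, "pretreatment_comparison.csv"),
                     row.names = FALSE)
  }
  attr(out, "reports") <- reports
  out
}

#' Run a stage, prefixing errors with the stage name
#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    msg <- conditionMessage(e)
    if (startsWith(msg, "stage ")) stop(e)
    stop(sprintf("stage %s: %s", name, msg), call. = FALSE)
  })
}

#' Serialise a report's artifacts
#' @noRd
write_artifacts <- function(report, config, mode) {
  if (is.null(config$outdir)) return(invisible(NULL))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  scalar <- report[vapply(report, function(v)
    is.numeric(v) && length(v) <= 3 || is.character(v), logical(1))]
  jsonlite::write_json(scalar, file.path(config$outdir,
                                         paste0(mode, "_report.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(report$confusion)) {
    utils::write.csv(report$confusion,
                     file.path(config$outdir, paste0(mode, "_confusion.csv")))
  }
  for (nm in names(report$traces)) {
    tr <- report$traces[[nm]]
    if (is.null(tr)) next
    if (!is.data.frame(tr)) tr <- data.frame(iteration = seq_along(tr) - 1L,
                                             gbest_fitness = tr)
    utils::write.csv(tr, file.path(config$outdir,
                                   paste0(mode, "_", nm, "_trace.csv")),
                     row.names = FALSE)
  }
  cfg <- config
  cfg$data <- if (!is.null(cfg$data)) "<in-memory spectrum_set>" else NULL
  jsonlite::write_json(unclass_deep(cfg),
                       file.path(config$outdir,
                                 paste0(mode, "_resolved_config.json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(NULL)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(x, unclass_deep) else x
}
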