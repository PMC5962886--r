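#' RBF-SVM classifier configuration
#'
#' @param c_grid SVM cost values (default `2^(-8:8)`).
#' @param g_grid RBF kernel gamma values (default `2^(-8:8)`).
#' @param inner_folds stratified folds for the inner grid search
#'   (default 10).
#' @param seed RNG seed controlling fold assignment.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(c_grid = 2^(-8:8), g_grid = 2^(-8:8),
                              inner_folds = 10, seed = 1) {
  if (length(c_grid) == 0 || length(g_grid) == 0)
    stop_hn("hn_config_error", "parameter grids must be nonempty")
  if (inner_folds < 2)
    stop_hn("hn_config_error", "inner_folds must be >= 2")
  structure(list(c_grid = sort(c_grid), g_grid = sort(g_grid),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Standardize features with training statistics only
#'
#' Per-feature z-scoring using the training mean and standard deviation;
#' test rows are transformed with the training statistics (never their
#' own), so no information leaks from held-out subjects. A zero-variance
#' training feature maps to 0 everywhere.
#'
#' @param train a [feature_table()].
#' @param test_rows optional [feature_table()] with the same features.
#' @return List with standardized `train` and (if given) `test` tables.
#' @export
standardize_features <- function(train, test_rows = NULL) {
  stopifnot(inherits(train, "feature_table"))
  mu <- colMeans(train$values)
  sdv <- apply(train$values, 2L, stats::sd)
  zv <- sdv == 0 | is.na(sdv)
  sdv[zv] <- 1
  tr <- sweep(sweep(train$values, 2L, mu, "-"), 2L, sdv, "/")
  tr[, zv] <- 0
  out <- list(train = feature_table(tr, train$labels, train$feature_names))
  if (!is.null(test_rows)) {
    te <- sweep(sweep(test_rows$values, 2L, mu, "-"), 2L, sdv, "/")
    te[, zv] <- 0
    out$test <- feature_table(te, test_rows$labels, test_rows$feature_names)
  }
  out
}

fit_svm <- function(x, y, cost, gamma) {
  e1071::svm(x = x, y = factor(y, levels = c("control", "patient")),
             type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

# Deterministic stratified fold ids; K is capped at the smaller class size
# so every fold keeps both classes.
stratified_folds <- function(labels, K, seed) {
  K <- min(K, min(table(labels)))
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(K), length(idx)))
    }
  })
  folds
}

#' Exhaustive (c, g) grid search by stratified K-fold cross-validation
#'
#' Evaluates every cost/gamma pair by inner cross-validated accuracy on the
#' training table and returns the best; ties break toward smaller `c`, then
#' smaller `g`. Deterministic given `config$seed`.
#'
#' @param train a [feature_table()] containing both classes.
#' @param config a [classifier_config()].
#' @return List `c`, `g`, `cv_accuracy` (fraction in `[0, 1]`).
#' @export
grid_search_cv <- function(train, config = classifier_config()) {
  stopifnot(inherits(train, "feature_table"))
  y <- train$labels
  if (length(unique(y)) < 2L)
    stop_hn("hn_schema_error", "grid search needs both classes present")
  folds <- stratified_folds(y, config$inner_folds, config$seed)
  K <- max(folds)
  best <- list(c = NA_real_, g = NA_real_, cv_accuracy = -1)
  for (cc in config$c_grid) for (gg in config$g_grid) {
    correct <- 0L
    for (k in seq_len(K)) {
      tr <- folds != k
      if (length(unique(y[tr])) < 2L) next
      fit <- fit_svm(train$values[tr, , drop = FALSE], y[tr], cc, gg)
      pred <- stats::predict(fit, train$values[!tr, , drop = FALSE])
      correct <- correct + sum(as.character(pred) == y[!tr])
    }
    acc <- correct / length(y)
    if (acc > best$cv_accuracy + 1e-12) best <- list(c = cc, g = gg, cv_accuracy = acc)
  }
  best
}

#' Nested leave-one-subject-out evaluation of an RBF-SVM
#'
#' For each held-out subject, the remaining subjects are standardized with
#' their own statistics, the (c, g) grid search runs inside that training
#' set, an RBF-SVM is fitted with the chosen pair, and the held-out subject
#' (transformed with the training statistics) is predicted. Patients are
#' the positive class.
#'
#' @param table a [feature_table()] with at least 2 subjects per class.
#' @param config a [classifier_config()].
#' @return Object of class `eval_result`: percentages `accuracy`,
#'   `sensitivity`, `specificity`, `bac`; `predictions`; per-fold chosen
#'   `parameters`; confusion counts `tp`, `tn`, `fp`, `fn`.
#' @export
loocv_evaluate <- function(table, config = classifier_config()) {
  stopifnot(inherits(table, "feature_table"))
  y <- table$labels
  if (min(base::table(factor(y, c("control", "patient")))) < 2L)
    stop_hn("hn_schema_error", "need >= 2 subjects per class for LOOCV")
  n <- nrow(table$values)
  preds <- character(n)
  params <- vector("list", n)
  for (i in seq_len(n)) {
    tr_tab <- feature_table(table$values[-i, , drop = FALSE], y[-i],
                            table$feature_names)
    te_tab <- feature_table(table$values[i, , drop = FALSE], y[i],
                            table$feature_names)
    std <- standardize_features(tr_tab, te_tab)
    pick <- grid_search_cv(std$train, config)
    fit <- fit_svm(std$train$values, std$train$labels, pick$c, pick$g)
    preds[i] <- as.character(stats::predict(fit, std$test$values))
    params[[i]] <- pick
  }
  tp <- sum(preds == "patient" & y == "patient")
  tn <- sum(preds == "control" & y == "control")
  fp <- sum(preds == "patient" & y == "control")
  fn <- sum(preds == "control" & y == "patient")
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  structure(list(
    accuracy = 100 * (tp + tn) / n,
    sensitivity = sens, specificity = spec,
    bac = compute_bac(sens, spec),
    predictions = stats::setNames(preds, rownames(table$values)),
    parameters = params,
    tp = tp, tn = tn, fp = fp, fn = fn
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(paste0("<eval_result> accuracy %.2f%%, sensitivity %.2f%%, ",
                     "specificity %.2f%%, BAC %.3f%%\n"),
              x$accuracy, x$sensitivity, x$specificity, x$bac))
  invisible(x)
}

#' Balanced accuracy
#'
#' Arithmetic mean of sensitivity and specificity (both in percent);
#' insensitive to class imbalance.
#'
#' @param sensitivity,specificity percentages in `[0, 100]`.
#' @return Balanced accuracy in percent.
#' @export
compute_bac <- function(sensitivity, specificity) {
  if (sensitivity < 0 || sensitivity > 100 || specificity < 0 || specificity > 100)
    stop_hn("hn_config_error", "sensitivity/specificity must lie in [0, 100]")
  (sensitivity + specificity) / 2
}
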