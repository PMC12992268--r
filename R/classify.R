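# Low-dimensional visualized classifiers on selected features: linear SVM,
# linear discriminant analysis, a shallow decision tree, and Gaussian naive
# Bayes, evaluated by resubstitution accuracy and stratified five-fold
# cross-validation, with an exportable 2D decision-boundary grid.

.MODELS <- c("linear_svm", "lda", "decision_tree", "gaussian_nb")

#' Classifier specification
#'
#' @param model One of `"linear_svm"` (linear kernel, C = 1), `"lda"`
#'   (equal priors), `"decision_tree"` (at most 3 splits), `"gaussian_nb"`
#'   (per-class normal densities).
#' @param features Nonempty character vector of feature column names (e.g.
#'   `c("F7", "F8")`).
#' @param standardize Z-score features on training folds; defaults on for
#'   all models except trees (split points are scale-equivariant).
#' @param folds Cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @param stratified Stratify folds by group.
#' @return An object of class `classifier_spec`.
#' @examples
#' classifier_spec("lda", c("F7", "F8"))
#' @export
classifier_spec <- function(model = .MODELS, features,
                            standardize = NULL, folds = 5, seed = 20,
                            stratified = TRUE) {
  model <- match.arg(model)
  if (length(features) < 1) stop("'features' must be nonempty")
  if (is.null(standardize)) standardize <- model != "decision_tree"
  structure(list(model = model, features = features,
                 standardize = standardize, folds = as.integer(folds),
                 seed = as.integer(seed), stratified = stratified),
            class = "classifier_spec")
}

# fit one model on a numeric matrix / factor
.fit_model <- function(model, x, y) {
  df <- data.frame(x, check.names = FALSE)
  switch(model,
    linear_svm = e1071::svm(x, y, kernel = "linear", cost = 1,
                            scale = FALSE, type = "C-classification"),
    lda = MASS::lda(x, grouping = y, prior = c(0.5, 0.5)),
    decision_tree = {
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = 2,
                                                  minsplit = 4, cp = 0,
                                                  xval = 0))
    },
    gaussian_nb = e1071::naiveBayes(x, y))
}

.predict_model <- function(model, fit, x) {
  df <- data.frame(x, check.names = FALSE)
  switch(model,
    linear_svm = stats::predict(fit, x),
    lda = stats::predict(fit, x)$class,
    decision_tree = stats::predict(fit, df, type = "class"),
    gaussian_nb = stats::predict(fit, x))
}

# deterministic stratified fold assignment
.make_folds <- function(y, k, seed, stratified) {
  set.seed(seed)
  fold <- integer(length(y))
  if (stratified) {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample(seq_along(y))] <- rep_len(seq_len(k), length(y))
  }
  fold
}

#' Classification metrics from a confusion matrix
#'
#' @param tp,fn True positives (cases called cases) and false negatives.
#' @param tn,fp True negatives (controls called controls) and false
#'   positives.
#' @return List with raw ratios (`accuracy`, `sensitivity`, `specificity`)
#'   and display percentages rounded to one decimal (`accuracy_pct`, ...).
#'   Zero-denominator rates are `NA`.
#' @examples
#' metrics_from_confusion(tp = 41, fn = 13, tn = 48, fp = 6)
#' @export
metrics_from_confusion <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0, tp + fn + tn + fp > 0)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- (tp + tn) / (tp + fn + tn + fp)
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       accuracy_pct = round(100 * acc, 1),
       sensitivity_pct = round(100 * sens, 1),
       specificity_pct = round(100 * spec, 1))
}

#' Fit, cross-validate and report a classifier
#'
#' Fits the specified model on the selected features of a feature table and
#' reports resubstitution accuracy with confusion counts (positive class =
#' `positive`), plus stratified k-fold cross-validation accuracy
#' (mean and sd over fold accuracies). Standardization parameters are
#' estimated on training folds only. Rows with missing selected features
#' are dropped and counted.
#'
#' @param spec A [classifier_spec()].
#' @param table A [build_feature_table()] result.
#' @param group_col Group label column.
#' @param positive Label of the positive (case) class.
#' @return An object of class `classifier_report`.
#' @export
fit_predict <- function(spec, table, group_col = "group",
                        positive = "MDD") {
  stopifnot(inherits(spec, "classifier_spec"))
  miss <- setdiff(spec$features, names(table))
  if (length(miss)) stop("features not in table: ",
                         paste(miss, collapse = ", "))
  x <- as.matrix(table[, spec$features, drop = FALSE])
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  y <- factor(table[[group_col]][keep])
  if (nlevels(y) != 2) stop("exactly two groups are required")
  y <- stats::relevel(y, ref = setdiff(levels(y), positive))
  zfit <- function(m) list(mu = colMeans(m), sd = apply(m, 2, stats::sd))
  zapp <- function(m, z) sweep(sweep(m, 2, z$mu), 2, pmax(z$sd, 1e-12), "/")

  # resubstitution
  xr <- if (spec$standardize) zapp(x, zfit(x)) else x
  fit <- .fit_model(spec$model, xr, y)
  pred <- .predict_model(spec$model, fit, xr)
  tp <- sum(pred == positive & y == positive)
  fn <- sum(pred != positive & y == positive)
  tn <- sum(pred != positive & y != positive)
  fp <- sum(pred == positive & y != positive)
  metrics <- metrics_from_confusion(tp, fn, tn, fp)

  # stratified cross-validation
  fold <- .make_folds(y, spec$folds, spec$seed, spec$stratified)
  cv_acc <- numeric(spec$folds)
  for (k in seq_len(spec$folds)) {
    tr <- fold != k; te <- fold == k
    if (length(unique(y[tr])) < 2)
      stop("a training fold contains one class only; use stratified folds ",
           "or more samples per group")
    xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    if (spec$standardize) {
      z <- zfit(xtr); xtr <- zapp(xtr, z); xte <- zapp(xte, z)
    }
    f <- .fit_model(spec$model, xtr, y[tr])
    cv_acc[k] <- mean(.predict_model(spec$model, f, xte) == y[te])
  }
  structure(list(
    spec = spec, n = length(y), n_dropped = sum(!keep),
    fit = fit, standardize = if (spec$standardize) zfit(x) else NULL,
    confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
    accuracy = metrics$accuracy, sensitivity = metrics$sensitivity,
    specificity = metrics$specificity,
    accuracy_pct = metrics$accuracy_pct,
    sensitivity_pct = metrics$sensitivity_pct,
    specificity_pct = metrics$specificity_pct,
    cv_fold_accuracy = cv_acc, cv_accuracy_mean = mean(cv_acc),
    cv_accuracy_sd = stats::sd(cv_acc), positive = positive),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("%s on {%s}: accuracy %.1f%% | CV %.1f%% +/- %.1f%%\n",
              x$spec$model, paste(x$spec$features, collapse = ", "),
              x$accuracy_pct, 100 * x$cv_accuracy_mean,
              100 * x$cv_accuracy_sd))
  cat(sprintf("  sensitivity %.1f%% (TP %d/%d), specificity %.1f%% (TN %d/%d)\n",
              x$sensitivity_pct, x$confusion["tp"],
              x$confusion["tp"] + x$confusion["fn"],
              x$specificity_pct, x$confusion["tn"],
              x$confusion["tn"] + x$confusion["fp"]))
  invisible(x)
}

#' Decision-boundary grid for a fitted 2D classifier
#'
#' Evaluates a fitted two-feature classifier on a regular grid spanning the
#' observed feature ranges extended by 10%, the serializable form of the
#' scatter-plus-boundary plots used to visualize low-dimensional
#' classifiers.
#'
#' @param report A [fit_predict()] report whose spec has exactly 2
#'   features.
#' @param table The feature table used for the ranges.
#' @param resolution Grid points per axis.
#' @return data.frame with the two feature coordinates and the predicted
#'   `label` at each grid point.
#' @export
boundary_grid <- function(report, table, resolution = 101) {
  spec <- report$spec
  if (length(spec$features) != 2)
    stop("boundary_grid requires exactly 2 features")
  x <- as.matrix(table[, spec$features, drop = FALSE])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  rng <- apply(x, 2, range)
  for (j in 1:2) {
    if (diff(rng[, j]) == 0)
      stop("feature '", spec$features[j], "' has zero range")
  }
  pad <- 0.1 * (rng[2, ] - rng[1, ])
  g1 <- seq(rng[1, 1] - pad[1], rng[2, 1] + pad[1], length.out = resolution)
  g2 <- seq(rng[1, 2] - pad[2], rng[2, 2] + pad[2], length.out = resolution)
  grid <- as.matrix(expand.grid(g1, g2))
  colnames(grid) <- spec$features
  gz <- if (!is.null(report$standardize))
    sweep(sweep(grid, 2, report$standardize$mu), 2,
          pmax(report$standardize$sd, 1e-12), "/") else grid
  lab <- .predict_model(spec$model, report$fit, gz)
  out <- data.frame(grid, label = as.character(lab),
                    stringsAsFactors = FALSE)
  names(out)[1:2] <- spec$features
  out
}
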