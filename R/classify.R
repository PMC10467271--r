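#' Canonical 79-feature names
#'
#' 9 global AUC metrics followed by the 5 nodal AUC metrics for each of the
#' `n_channels` channels, in fixed order.
#'
#' @param n_channels Number of channels.
#' @return Character vector of feature names
#'   (`"global.Cp"`, ..., `"nodal.Bc.ch14"`).
#' @export
feature_names <- function(n_channels = 14) {
  c(paste0("global.", .global_metric_names),
    as.vector(vapply(.nodal_metric_names, function(m)
      sprintf("nodal.%s.ch%02d", m, seq_len(n_channels)),
      character(n_channels))))
}

#' Assemble the per-subject feature table for one state
#'
#' Collects the AUC values of the 9 global and 5 x 14 nodal metrics into a
#' subjects x 79 matrix with canonical column order. Missing AUCs (e.g.
#' assortativity or hierarchy undefined at some threshold) are imputed by
#' the column median; the imputation is logged in the `imputation_log`
#' attribute. Subjects missing the requested state are excluded with a
#' warning.
#'
#' @param metric_sets Named list (by subject id) of per-subject lists with
#'   `rest` and `task` [metric_sweep()] results.
#' @param state `"task"` or `"rest"`.
#' @param labels Named group vector (`"PSD"`/`"nonPSD"`) or a vector aligned
#'   with `metric_sets`.
#' @return An object of class `feature_table`: numeric matrix with
#'   `labels` and `imputation_log` attributes.
#' @export
assemble_features <- function(metric_sets, state = c("task", "rest"),
                              labels) {
  state <- match.arg(state)
  have <- vapply(metric_sets, function(ms) !is.null(ms[[state]]), logical(1))
  if (!all(have)) {
    warning("excluding subject(s) without ", state, " state: ",
            paste(names(metric_sets)[!have], collapse = ", "))
    metric_sets <- metric_sets[have]
    labels <- labels[have]
  }
  rows <- lapply(metric_sets, function(ms) {
    m <- ms[[state]]
    c(m$auc$global, as.vector(t(m$auc$nodal)))
  })
  x <- do.call(rbind, rows)
  nch <- ncol(metric_sets[[1]][[state]]$auc$nodal)
  colnames(x) <- feature_names(nch)
  rownames(x) <- names(metric_sets)

  imput <- character(0)
  for (j in seq_len(ncol(x))) {
    nas <- which(!is.finite(x[, j]))
    if (length(nas)) {
      med <- stats::median(x[is.finite(x[, j]), j])
      if (!is.finite(med)) med <- 0
      x[nas, j] <- med
      imput <- c(imput, sprintf("%s: %d value(s) imputed with median %.4g",
                                colnames(x)[j], length(nas), med))
    }
  }
  structure(x, class = c("feature_table", "matrix"),
            labels = labels, imputation_log = imput)
}

# stratified fold assignment; re-drawn until every training fold contains
# both classes
stratified_folds <- function(labels, n_folds, max_tries = 100) {
  n <- length(labels)
  for (try in seq_len(max_tries)) {
    fold <- integer(n)
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
    ok <- all(vapply(seq_len(n_folds), function(f)
      length(unique(labels[fold != f])) == 2, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build folds with both classes in every training set")
}

#' Cost-sensitive SVM evaluation under repeated stratified cross-validation
#'
#' Per repeat, subjects are split into `n_folds` stratified folds. Strictly
#' within each training fold the features are standardized, projected onto
#' the principal components retaining `variance_retained` of the variance,
#' and a support vector machine with class weights inversely proportional to
#' the training class frequencies is fitted; the held-out fold is scored
#' with the training fold's transformations. Accuracy is the fraction of
#' correctly identified subjects; the report carries the per-fold
#' accuracies and the mean and SD of the per-repeat accuracies.
#'
#' @param features A [assemble_features()] table (or plain matrix).
#' @param labels Group labels; defaults to the table's `labels` attribute.
#' @param n_folds,n_repeats Cross-validation geometry (8 x 10 by default).
#' @param variance_retained PCA variance fraction kept in training folds.
#' @param cost_mode `"balanced"` (inverse-frequency class weights) or
#'   `"none"`.
#' @param kernel SVM kernel (`"linear"` default, `"radial"` available).
#' @param cost SVM misclassification cost parameter.
#' @param seed Seed; identical seeds give identical reports.
#' @return An object of class `classification_report`: list with
#'   `fold_accuracy` (repeats x folds), `repeat_accuracy`, `mean_accuracy`,
#'   `sd_accuracy` and `config`.
#' @export
fit_eval <- function(features, labels = attr(features, "labels"),
                     n_folds = 8, n_repeats = 10,
                     variance_retained = 0.95,
                     cost_mode = c("balanced", "none"),
                     kernel = "linear", cost = 1, seed = 1) {
  cost_mode <- match.arg(cost_mode)
  x <- unclass(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("need exactly 2 classes")
  if (min(table(labels)) < 2) stop("need >= 2 subjects per class")
  n <- nrow(x)
  stopifnot(length(labels) == n)
  set.seed(seed)

  fold_acc <- matrix(NA_real_, n_repeats, n_folds)
  repeat_acc <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(as.character(labels), n_folds)
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- !tr
      if (!any(te)) { fold_acc[r, f] <- NA; next }
      mu <- colMeans(x[tr, , drop = FALSE])
      sd_ <- apply(x[tr, , drop = FALSE], 2, stats::sd)
      sd_[sd_ == 0] <- 1
      xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sd_, "/")
      xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sd_, "/")
      pc <- stats::prcomp(xtr, center = FALSE, scale. = FALSE)
      cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
      k <- max(1L, which(cum >= variance_retained)[1])
      ptr <- xtr %*% pc$rotation[, seq_len(k), drop = FALSE]
      pte <- xte %*% pc$rotation[, seq_len(k), drop = FALSE]
      w <- if (cost_mode == "balanced") {
        tb <- table(labels[tr])
        ww <- sum(tb) / (length(tb) * tb)
        stats::setNames(as.numeric(ww), names(tb))
      } else NULL
      fit <- e1071::svm(x = ptr, y = labels[tr], kernel = kernel,
                        cost = cost, class.weights = w, scale = FALSE)
      pred <- stats::predict(fit, pte)
      hit <- sum(pred == labels[te])
      fold_acc[r, f] <- hit / sum(te)
      correct <- correct + hit
    }
    repeat_acc[r] <- correct / n
  }
  structure(
    list(fold_accuracy = fold_acc,
         repeat_accuracy = repeat_acc,
         mean_accuracy = mean(repeat_acc),
         sd_accuracy = stats::sd(repeat_acc),
         config = list(n_folds = n_folds, n_repeats = n_repeats,
                       variance_retained = variance_retained,
                       cost_mode = cost_mode, kernel = kernel,
                       cost = cost, seed = seed)),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification: %.2f%% +/- %.2f%% accuracy (%d-fold CV x %d repeats, %s SVM)\n",
              100 * x$mean_accuracy, 100 * x$sd_accuracy,
              x$config$n_folds, x$config$n_repeats, x$config$kernel))
  invisible(x)
}
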