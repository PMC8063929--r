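#' Nested cross-validation configuration
#'
#' @param outer_folds,inner_folds Fold counts (both >= 2). The study design
#'   is 10 outer x 9 inner for the risk problem and 5 outer x 4 inner for
#'   the outcome problem.
#' @param stratified Keep per-fold class ratios within one subject of the
#'   global ratio.
#' @param seed Integer seed driving all fold shuffles.
#' @param knn_grid Candidate neighbour counts.
#' @param svm_grid Data frame of SVM candidates (columns `kernel`, `C`,
#'   `gamma_scale`, `degree`); `NULL` for the default grid — linear,
#'   quadratic and cubic polynomial, and Gaussian at three width presets
#'   (gamma = `gamma_scale / n_features`), each crossed with the cost grid.
#' @param C_grid Cost values for the default SVM grid.
#' @param selection_k In-fold weight-correlation selection: number of
#'   features kept; `NULL` disables selection (all columns used).
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 10L, inner_folds = 9L,
                      stratified = TRUE, seed = 1L,
                      knn_grid = seq(1L, 21L, 2L), svm_grid = NULL,
                      C_grid = c(0.01, 0.1, 1, 10, 100),
                      selection_k = NULL) {
  if (outer_folds < 2L || inner_folds < 2L)
    stop("outer_folds and inner_folds must both be >= 2")
  if (length(knn_grid) < 1L) stop("knn_grid must be non-empty")
  if (is.null(svm_grid)) {
    base <- rbind(
      data.frame(kernel = "linear", gamma_scale = NA_real_, degree = NA_integer_),
      data.frame(kernel = "polynomial", gamma_scale = 1, degree = c(2L, 3L)),
      data.frame(kernel = "radial", gamma_scale = c(0.25, 1, 4),
                 degree = NA_integer_))
    svm_grid <- merge(base, data.frame(C = C_grid), by = NULL)
    # simpler kernels first, then smaller C (tie-break order)
    kord <- match(svm_grid$kernel, c("linear", "polynomial", "radial"))
    svm_grid <- svm_grid[order(kord, svm_grid$degree, svm_grid$gamma_scale,
                               svm_grid$C, na.last = FALSE), ]
    rownames(svm_grid) <- NULL
  }
  if (nrow(svm_grid) < 1L) stop("svm_grid must be non-empty")
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 stratified = stratified, seed = as.integer(seed),
                 knn_grid = sort(as.integer(knn_grid)), svm_grid = svm_grid,
                 selection_k = selection_k),
            class = "cv_config")
}

# fold assignment (1..k) per row; stratified round-robin after a per-class
# shuffle, so per-fold class counts differ by at most one subject
make_folds <- function(labels, k, stratified = TRUE) {
  n <- length(labels)
  fold <- integer(n)
  if (stratified) {
    # continue the round-robin offset across classes so total fold sizes
    # stay within one of each other as well as the per-class counts
    off <- 0L
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- (off + seq_along(idx) - 1L) %% k + 1L
      off <- off + length(idx)
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

# fit the given grid point on (train, labels) and predict test rows
fit_predict <- function(classifier, params, train, labels, test) {
  if (classifier == "knn") {
    k <- min(params$k, nrow(train))
    knn_classify(train, labels, test, k)
  } else {
    gamma <- if (is.na(params$gamma_scale)) NULL
             else params$gamma_scale / ncol(train)
    degree <- if (is.na(params$degree)) 3L else params$degree
    svm_classify(train, labels, test, kernel = params$kernel,
                 C = params$C, gamma = gamma, degree = degree)
  }
}

grid_as_list <- function(classifier, config) {
  if (classifier == "knn")
    lapply(config$knn_grid, function(k) list(k = k))
  else
    lapply(seq_len(nrow(config$svm_grid)), function(i)
      as.list(config$svm_grid[i, ]))
}

# prepare one training fold: standardise, select features in-fold
fold_prep <- function(train, labels, config) {
  sc <- standardizer(train)
  tr <- predict(sc, train)
  if (!is.null(config$selection_k)) {
    rk <- rank_and_select(tr, labels, min(config$selection_k, ncol(tr)))
    list(scaler = sc, selected = rk$selected, ranking = rk,
         train = tr[, rk$selected, drop = FALSE])
  } else {
    list(scaler = sc, selected = colnames(tr), ranking = NULL, train = tr)
  }
}

#' Nested cross-validated classification
#'
#' Outer folds partition the subjects exactly once into test sets. Within
#' each outer training fold, standardisation parameters, the
#' weight-correlation feature ranking, and the hyperparameter choice (inner
#' CV over the grid, best mean inner accuracy, ties to the simpler model)
#' are computed from that training fold only — outer test rows never
#' influence them. Performance is computed from the pooled outer-test
#' predictions.
#'
#' @param features Numeric matrix/data.frame (rows = subjects, named
#'   columns).
#' @param labels Class label per row (two classes).
#' @param classifier `"knn"` or `"svm"`.
#' @param config A [cv_config()].
#' @param positive_class Label treated as positive in the confusion counts.
#' @return Object of class `evaluation_report`: per-fold details (`folds`),
#'   pooled `confusion`, `accuracy`, `sensitivity`, `specificity`,
#'   `predictions` (per subject), and `n`.
#' @export
nested_cv <- function(features, labels, classifier = c("knn", "svm"),
                      config = cv_config(), positive_class) {
  classifier <- match.arg(classifier)
  features <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(features)
  if (missing(positive_class)) positive_class <- sort(unique(labels))[1L]
  grid <- grid_as_list(classifier, config)
  with_seed(config$seed, {
    fold <- make_folds(labels, config$outer_folds, config$stratified)
    if (min(table(fold)) < 1L) stop("empty outer fold")
    folds <- vector("list", config$outer_folds)
    pred_all <- character(n)
    for (f in seq_len(config$outer_folds)) {
      tr_idx <- which(fold != f)
      te_idx <- which(fold == f)
      tr_lab <- labels[tr_idx]
      if (length(unique(tr_lab)) < 2L)
        stop("outer training fold lost a class; use stratified folds")
      # inner CV over the grid
      inner_fold <- make_folds(tr_lab, config$inner_folds, config$stratified)
      correct <- integer(length(grid))
      total <- 0L
      for (g in seq_len(config$inner_folds)) {
        itr <- tr_idx[inner_fold != g]
        iva <- tr_idx[inner_fold == g]
        if (length(iva) == 0L || length(unique(labels[itr])) < 2L) next
        prep <- fold_prep(features[itr, , drop = FALSE], labels[itr], config)
        va <- predict(prep$scaler,
                      features[iva, , drop = FALSE])[, prep$selected,
                                                     drop = FALSE]
        for (gi in seq_along(grid)) {
          p <- fit_predict(classifier, grid[[gi]], prep$train, labels[itr], va)
          correct[gi] <- correct[gi] + sum(p == labels[iva])
        }
        total <- total + length(iva)
      }
      best <- which.max(correct)  # first max = simplest model in grid order
      # refit on the full outer training fold
      prep <- fold_prep(features[tr_idx, , drop = FALSE], tr_lab, config)
      te <- predict(prep$scaler,
                    features[te_idx, , drop = FALSE])[, prep$selected,
                                                      drop = FALSE]
      p <- fit_predict(classifier, grid[[best]], prep$train, tr_lab, te)
      pred_all[te_idx] <- p
      folds[[f]] <- list(test_idx = te_idx, predictions = p,
                         truth = labels[te_idx],
                         hyperparameters = grid[[best]],
                         inner_accuracy = correct[best] / max(total, 1L),
                         selected_features = prep$selected)
    }
    confusion <- confusion_counts(labels, pred_all, positive_class)
    metrics <- compute_metrics(confusion)
    structure(c(list(folds = folds, confusion = confusion,
                     predictions = pred_all, truth = labels, n = n,
                     classifier = classifier),
                metrics),
              class = "evaluation_report")
  })
}

#' Confusion counts for binary predictions
#'
#' @param truth,predicted Label vectors.
#' @param positive_class The positive label (high-risk in the risk problem,
#'   HR-ASD in the outcome problem).
#' @return List with `tp`, `tn`, `fp`, `fn`, `positive_class`.
#' @export
confusion_counts <- function(truth, predicted, positive_class) {
  tp <- sum(truth == positive_class & predicted == positive_class)
  tn <- sum(truth != positive_class & predicted != positive_class)
  fp <- sum(truth != positive_class & predicted == positive_class)
  fn <- sum(truth == positive_class & predicted != positive_class)
  list(tp = tp, tn = tn, fp = fp, fn = fn, positive_class = positive_class)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy = (tp+tn)/total; sensitivity = tp/(tp+fn); specificity =
#' tn/(tn+fp). A metric with a zero denominator is reported as `NA`
#' (undefined), not an error.
#'
#' @param confusion As from [confusion_counts()].
#' @return List with `accuracy`, `sensitivity`, `specificity`.
#' @export
compute_metrics <- function(confusion) {
  with(confusion, {
    total <- tp + tn + fp + fn
    list(accuracy = if (total > 0) (tp + tn) / total else NA_real_,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Nested-CV evaluation (%s, %d outer folds, n = %d)\n",
              x$classifier, length(x$folds), x$n))
  cat(sprintf("  accuracy %.4f | sensitivity %.4f | specificity %.4f (positive: %s)\n",
              x$accuracy, x$sensitivity, x$specificity,
              x$confusion$positive_class))
  invisible(x)
}

#' Balanced subsampling of the majority class
#'
#' Each repeat keeps every minority subject and draws `length(minority_ids)`
#' distinct majority subjects without replacement; draws are independent
#' across repeats and reproducible under `seed`.
#'
#' @param minority_ids,majority_ids Subject identifier vectors.
#' @param repeats Number of balanced sets (default 5).
#' @param seed Integer seed.
#' @return List of `repeats` character vectors, each of length
#'   `2 * length(minority_ids)`.
#' @export
balanced_resample <- function(minority_ids, majority_ids, repeats = 5L,
                              seed = 1L) {
  if (length(minority_ids) > length(majority_ids))
    stop("minority class is larger than majority class")
  with_seed(seed, lapply(seq_len(repeats), function(i)
    c(minority_ids, sample(majority_ids, length(minority_ids)))))
}
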