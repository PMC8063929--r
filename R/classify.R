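#' k-nearest-neighbour classification with Euclidean distance
#'
#' Majority vote among the `k` nearest training rows. A vote tie is broken
#' by the class of the nearest neighbour belonging to one of the tied
#' classes; equal distances are resolved by training-row order. Features
#' should be standardised beforehand ([standardizer()]): Euclidean distance
#' on raw mixed-unit features is scale-dominated.
#'
#' @param train Numeric matrix of training rows.
#' @param train_labels Labels, one per training row.
#' @param test Numeric matrix of rows to classify (same columns).
#' @param k Number of neighbours (1..nrow(train)).
#' @return Character vector of predicted labels.
#' @export
knn_classify <- function(train, train_labels, test, k) {
  train <- as.matrix(train); test <- as.matrix(test)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(train)) stop("k exceeds the number of training rows")
  train_labels <- as.character(train_labels)
  # squared Euclidean distances, test rows x train rows
  d2 <- outer(rowSums(test^2), rowSums(train^2), "+") -
    2 * tcrossprod(test, train)
  apply(d2, 1, function(dr) {
    nb <- order(dr)[seq_len(k)]
    votes <- table(train_labels[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    train_labels[nb][train_labels[nb] %in% top][1L]
  })
}

#' Support-vector-machine classification
#'
#' Thin wrapper over [e1071::svm()] (C-classification, no internal
#' rescaling). Kernels: `"linear"`, `"polynomial"` (quadratic/cubic via
#' `degree`), `"radial"` (Gaussian; width presets are expressed through
#' `gamma`).
#'
#' @param train,train_labels,test As in [knn_classify()].
#' @param kernel Kernel family.
#' @param C Soft-margin cost.
#' @param gamma Kernel coefficient for polynomial/radial kernels; default
#'   `1/ncol(train)`.
#' @param degree Polynomial degree (2 or 3).
#' @return Character vector of predicted labels.
#' @export
svm_classify <- function(train, train_labels, test,
                         kernel = c("linear", "polynomial", "radial"),
                         C = 1, gamma = NULL, degree = 3L) {
  kernel <- match.arg(kernel)
  train_labels <- factor(train_labels)
  if (nlevels(train_labels) < 2L)
    stop("SVM needs two classes in the training labels")
  if (is.null(gamma)) gamma <- 1 / ncol(as.matrix(train))
  fit <- e1071::svm(x = as.matrix(train), y = train_labels, scale = FALSE,
                    type = "C-classification", kernel = kernel,
                    cost = C, gamma = gamma, degree = degree, coef0 = 1)
  as.character(stats::predict(fit, as.matrix(test)))
}

#' Training-set z-score standardiser
#'
#' Computes per-column mean and standard deviation on training rows only;
#' `predict` applies them to any matrix. Constant columns are centred and
#' left unscaled.
#'
#' @param train Numeric matrix.
#' @return Object of class `standardizer` with a `predict` method.
#' @export
standardizer <- function(train) {
  train <- as.matrix(train)
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  structure(list(mean = mu, sd = sd), class = "standardizer")
}

#' @export
predict.standardizer <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(sweep(newdata, 2, object$mean), 2, object$sd, "/")
}
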