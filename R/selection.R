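#' Weight correlation of a feature with a binary label
#'
#' Absolute Pearson correlation between the feature column and the 0/1
#' label indicator (the point-biserial correlation). Lies in \[0, 1\]; a
#' constant feature is assigned weight 0 by convention.
#'
#' @param x Numeric feature column.
#' @param labels Binary labels: logical, 0/1 numeric, or a two-level factor
#'   (second level is treated as positive).
#' @return Scalar weight in \[0, 1\].
#' @export
weight_correlation <- function(x, labels) {
  y <- as_binary_labels(labels)
  if (length(x) != length(y)) stop("feature and label lengths differ")
  if (length(x) < 2L) stop("need at least 2 samples")
  if (all(y == 0) || all(y == 1)) stop("both classes must be present")
  if (stats::sd(x) == 0) return(0)
  abs(stats::cor(x, y))
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.numeric(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
    return(as.numeric(labels == levels(labels)[2L]))
  }
  u <- sort(unique(labels))
  if (length(u) > 2L) stop("labels must be binary")
  as.numeric(labels == u[length(u)])
}

#' Rank features by weight correlation and select the top k
#'
#' Computes the point-biserial weight of every column against the label,
#' sorts in descending weight (ties broken by ascending column index), and
#' keeps the first `k`. Call on training rows only; selection must never see
#' test data.
#'
#' @param features Numeric matrix or data.frame of feature columns (named).
#' @param labels Binary labels, one per row.
#' @param k Number of features to keep (1..ncol).
#' @return Object of class `feature_ranking`: `weights` (named, input
#'   order), `order` (column indices by descending weight), `k_selected`,
#'   `selected` (column names of the top k), `table` (rank/weight/condition/
#'   imf/feature data.frame when names parse as feature labels).
#' @export
rank_and_select <- function(features, labels, k) {
  features <- as.matrix(features)
  if (k < 1L || k > ncol(features))
    stop("k must be between 1 and the number of feature columns")
  w <- apply(features, 2, weight_correlation, labels = labels)
  ord <- order(-w, seq_along(w))
  sel <- ord[seq_len(k)]
  tab <- data.frame(rank = seq_along(ord), weight = w[ord],
                    column = colnames(features)[ord],
                    stringsAsFactors = FALSE)
  parsed <- tryCatch(parse_feature_labels(tab$column), error = function(e) NULL)
  if (!is.null(parsed) && !anyNA(parsed$imf)) tab <- cbind(tab, parsed)
  rownames(tab) <- NULL
  structure(list(weights = w, order = ord, k_selected = as.integer(k),
                 selected = colnames(features)[sel], table = tab),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("Feature ranking: top %d of %d columns by weight correlation\n",
              x$k_selected, length(x$weights)))
  print(utils::head(x$table, n))
  invisible(x)
}
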