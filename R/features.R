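#' IMF energy
#'
#' Sum of squared amplitudes, \eqn{\sum_k x_k^2} (microvolts squared). A
#' measure of oscillation strength over the epoch.
#'
#' @param x Numeric IMF waveform.
#' @return Nonnegative scalar; 0 only for the zero signal.
#' @export
imf_energy <- function(x) {
  if (length(x) == 0L) stop("empty waveform")
  sum(x^2)
}

#' Shannon entropy of squared IMF amplitudes
#'
#' \eqn{-\sum_k x_k^2 \log(x_k^2)} with the convention
#' \eqn{0 \cdot \log 0 = 0}; natural logarithm. The squared amplitudes are
#' used as-is (no normalisation to probabilities), so this is an unnormalised
#' complexity measure of the waveform.
#'
#' @param x Numeric IMF waveform.
#' @return Scalar entropy (unitless).
#' @export
shannon_entropy <- function(x) {
  if (length(x) == 0L) stop("empty waveform")
  p <- x^2
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Four distributional statistics of an IMF
#'
#' Sample mean; sample standard deviation (n - 1 denominator); skewness as
#' the third standardised moment using the population estimator
#' \eqn{m_3 / m_2^{3/2}} (0 when the signal is constant); and the fourth
#' central moment \eqn{m_4 = \frac{1}{n}\sum (x - \bar x)^4}.
#'
#' @param x Numeric IMF waveform, length >= 2.
#' @return Named numeric vector `mean`, `std`, `skewness`, `moment`.
#' @export
statistical_features <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  skew <- if (m2 == 0) 0 else mean(d^3) / m2^1.5
  c(mean = mu, std = stats::sd(x), skewness = skew, moment = mean(d^4))
}

imf_feature_names <- c("energy", "shannon_entropy", "mean", "std",
                       "skewness", "moment")

# all six features of one IMF, in canonical order
imf_features <- function(x) {
  st <- statistical_features(x)
  c(energy = imf_energy(x), shannon_entropy = shannon_entropy(x),
    st["mean"], st["std"], st["skewness"], st["moment"])
}

#' Canonical feature-column labels
#'
#' Condition-major, then IMF (1..n_imfs), then feature (energy,
#' shannon_entropy, mean, std, skewness, moment): with six conditions and
#' three IMFs, 6 x 3 x 6 = 108 columns named
#' `"<condition>|imf<j>|<feature>"`.
#'
#' @param conditions Condition names.
#' @param n_imfs IMFs per condition.
#' @return Character vector of column labels.
#' @export
feature_labels <- function(conditions = erp_conditions(), n_imfs = 3L) {
  as.vector(vapply(conditions, function(cond)
    as.vector(vapply(seq_len(n_imfs), function(j)
      sprintf("%s|imf%d|%s", cond, j, imf_feature_names),
      character(length(imf_feature_names)))),
    character(n_imfs * length(imf_feature_names))))
}

#' Parse feature-column labels into (condition, imf, feature) triples
#'
#' @param labels Labels as produced by [feature_labels()].
#' @return data.frame with columns `condition`, `imf` (integer), `feature`.
#' @export
parse_feature_labels <- function(labels) {
  parts <- strsplit(labels, "|", fixed = TRUE)
  data.frame(condition = vapply(parts, `[`, "", 1L),
             imf = as.integer(sub("imf", "", vapply(parts, `[`, "", 2L))),
             feature = vapply(parts, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Assemble the channels x features matrix for one subject
#'
#' For each of the six conditions, each channel's ERP is decomposed into
#' IMFs 1..3 and the six-feature battery is computed per IMF, giving
#' channels x 108 values in canonical column order. Decompositions yielding
#' fewer than `n_imfs` IMFs pad the missing modes with the zero waveform
#' (all-zero features).
#'
#' @param decompositions Nested list:
#'   `decompositions[[condition]][[channel]]` is an `imf_decomposition`.
#' @param conditions Condition names (order fixes column order).
#' @param n_imfs IMFs per condition (default 3).
#' @return Object of class `feature_matrix`: list with `subject_id` (may be
#'   `NA`), `values` (channels x 108 matrix, labelled columns), and
#'   `column_labels`.
#' @export
assemble_features <- function(decompositions, conditions = erp_conditions(),
                              n_imfs = 3L, subject_id = NA_character_) {
  missing <- setdiff(conditions, names(decompositions))
  if (length(missing))
    stop("missing decompositions for condition(s): ",
         paste(missing, collapse = ", "))
  n_channels <- length(decompositions[[conditions[1]]])
  labels <- feature_labels(conditions, n_imfs)
  values <- matrix(NA_real_, n_channels, length(labels),
                   dimnames = list(NULL, labels))
  nf <- length(imf_feature_names)
  for (ci in seq_along(conditions)) {
    chans <- decompositions[[conditions[ci]]]
    if (length(chans) != n_channels)
      stop("missing channel decompositions in condition ", conditions[ci])
    for (ch in seq_len(n_channels)) {
      dec <- chans[[ch]]
      if (!inherits(dec, "imf_decomposition"))
        stop(sprintf("missing decomposition at condition %s, channel %d",
                     conditions[ci], ch))
      for (j in seq_len(n_imfs)) {
        imf <- if (j <= length(dec$imfs)) dec$imfs[[j]]
               else rep(0, dec$source_length)
        col0 <- (ci - 1L) * n_imfs * nf + (j - 1L) * nf
        values[ch, col0 + seq_len(nf)] <- imf_features(imf)
      }
    }
  }
  structure(list(subject_id = subject_id, values = values,
                 column_labels = labels),
            class = "feature_matrix")
}

#' Reduce a feature matrix to one row by the maximum across channels
#'
#' Per feature column, keeps the (signed) maximum over channels and records
#' which channel attained it. Permutation of channels cannot change the
#' values.
#'
#' @param fm A `feature_matrix`.
#' @return Object of class `feature_vector`: list with `subject_id`,
#'   `values` (named numeric, one per column), `column_labels`,
#'   `argmax_channel` (integer per column).
#' @export
reduce_max_across_channels <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$values) < 1L) stop("feature matrix has no channels")
  arg <- apply(fm$values, 2, which.max)
  vals <- fm$values[cbind(arg, seq_len(ncol(fm$values)))]
  names(vals) <- fm$column_labels
  structure(list(subject_id = fm$subject_id, values = vals,
                 column_labels = fm$column_labels,
                 argmax_channel = as.integer(arg)),
            class = "feature_vector")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix %s: %d channels x %d features\n",
              x$subject_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("Feature vector %s: %d features (max across channels)\n",
              x$subject_id, length(x$values)))
  invisible(x)
}

#' Decompose every channel of an ERP and extract its feature block
#'
#' Convenience wrapper: EMD per channel, then features. Returns the list of
#' decompositions for one condition, suitable for [assemble_features()].
#'
#' @param erp An `erp_waveform`.
#' @param config A [sift_config()].
#' @return List of `imf_decomposition`, one per channel.
#' @export
decompose_erp <- function(erp, config = sift_config()) {
  lapply(seq_len(nrow(erp$data)), function(ch)
    emd_decompose(erp$data[ch, ], config))
}
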