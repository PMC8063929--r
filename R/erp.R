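#' Exclude subjects with too few trials in any condition
#'
#' A subject is dropped when any condition has fewer than `min_trials`
#' retained trials. Every subject must have one recording per condition.
#'
#' @param recordings List of [epoched_recording()]s covering a full
#'   subjects x conditions grid.
#' @param conditions Condition names expected for every subject.
#' @param min_trials Exclusion threshold (default 10).
#' @return List with `retained` (subject ids), `excluded` (subject ids) and
#'   `log` (data.frame subject_id, condition, n_trials for every violation).
#' @export
exclude_low_trial_subjects <- function(recordings,
                                       conditions = erp_conditions(),
                                       min_trials = 10L) {
  counts <- data.frame(
    subject_id = vapply(recordings, function(r) r$subject_id, ""),
    condition = vapply(recordings, function(r) r$condition, ""),
    n_trials = vapply(recordings, function(r) dim(r$data)[1], 0L),
    stringsAsFactors = FALSE)
  subjects <- unique(counts$subject_id)
  have <- table(counts$subject_id)
  if (any(have != length(conditions)))
    stop("incomplete cohort: subject(s) missing conditions: ",
         paste(names(have)[have != length(conditions)], collapse = ", "))
  log <- counts[counts$n_trials < min_trials, , drop = FALSE]
  rownames(log) <- NULL
  excluded <- unique(log$subject_id)
  list(retained = setdiff(subjects, excluded), excluded = excluded, log = log)
}

#' Re-reference epoched data to the common average
#'
#' Subtracts, at every sample, the mean across channels, so the channel mean
#' is zero everywhere. Applied before trial averaging.
#'
#' @param x `channels x samples` matrix or `trials x channels x samples`
#'   array.
#' @return Same shape as input.
#' @export
rereference_to_average <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) < 2L) stop("average re-reference needs >= 2 channels")
    return(sweep(x, 2, colMeans(x)))
  }
  d <- dim(x)
  if (length(d) != 3L) stop("expected a matrix or a 3-d array")
  if (d[2] < 2L) stop("average re-reference needs >= 2 channels")
  mu <- apply(x, c(1, 3), mean)           # trials x samples
  x - aperm(array(mu, c(d[1], d[3], d[2])), c(1, 3, 2))
}

#' Baseline-correct epoched data
#'
#' Per trial and channel, subtracts the mean over the pre-stimulus baseline
#' window (default \[-200, 0) ms) so that the baseline mean is zero.
#'
#' @param x `channels x samples` matrix or `trials x channels x samples`
#'   array.
#' @param fs Sampling rate, Hz.
#' @param t0 1-based sample index of stimulus onset.
#' @param window Baseline limits in ms, half-open `[from, to)`.
#' @return Same shape as input.
#' @export
baseline_correct <- function(x, fs, t0, window = c(-200, 0)) {
  d <- if (is.matrix(x)) c(1L, dim(x)) else dim(x)
  n_samples <- d[3]
  from <- t0 + round(window[1] / 1000 * fs)
  to <- t0 + round(window[2] / 1000 * fs) - 1L
  if (from < 1L || to > n_samples || to < from)
    stop("empty or out-of-range baseline window")
  idx <- from:to
  if (is.matrix(x)) return(x - rowMeans(x[, idx, drop = FALSE]))
  mu <- apply(x[, , idx, drop = FALSE], c(1, 2), mean)  # trials x channels
  x - array(mu, d)
}

#' Average trials into an ERP waveform
#'
#' @param recording An [epoched_recording()] (or a trials x channels x
#'   samples array) with at least one trial.
#' @param subject_id,condition,fs,t0 Metadata when a bare array is given.
#' @return Object of class `erp_waveform`: list with `subject_id`,
#'   `condition`, `data` (`channels x samples`), `fs`, `t0`.
#' @export
average_trials <- function(recording, subject_id = NULL, condition = NULL,
                           fs = NULL, t0 = NULL) {
  if (inherits(recording, "epoched_recording")) {
    dat <- recording$data
    subject_id <- recording$subject_id
    condition <- recording$condition
    fs <- recording$fs
    t0 <- recording$t0
  } else dat <- recording
  if (dim(dat)[1] < 1L) stop("cannot average zero trials")
  erp <- apply(dat, c(2, 3), mean)
  structure(list(subject_id = subject_id, condition = condition,
                 data = erp, fs = fs, t0 = t0),
            class = "erp_waveform")
}

#' Epochs-to-ERP processing for one recording
#'
#' Fixed order: re-reference to the common average, baseline-correct each
#' trial over \[-200, 0) ms, then average trials. (Baseline correction and
#' averaging commute — both are linear — but the per-trial order is kept for
#' fidelity to standard ERP practice.)
#'
#' @param recording An [epoched_recording()].
#' @param baseline Baseline window in ms.
#' @return An `erp_waveform`.
#' @export
epochs_to_erp <- function(recording, baseline = c(-200, 0)) {
  x <- rereference_to_average(recording$data)
  x <- baseline_correct(x, recording$fs, recording$t0, baseline)
  average_trials(x, recording$subject_id, recording$condition,
                 recording$fs, recording$t0)
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("ERP %s / %s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}
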