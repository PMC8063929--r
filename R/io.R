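#' Write a cohort to long-format CSV plus a label manifest
#'
#' One row per (subject, condition, trial, channel, sample) with the value
#' in microvolts — a flat interchange format; sizeable for large cohorts,
#' intended for small exports and round-trip testing. The manifest holds
#' one row per subject: `subject_id`, `group`, `outcome_known`.
#'
#' @param cohort An `erp_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`data`, `manifest`).
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- lapply(cohort$recordings, function(r) {
    d <- dim(r$data)
    data.table::data.table(
      subject = r$subject_id, condition = r$condition,
      trial = rep(seq_len(d[1]), times = d[2] * d[3]),
      channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      sample = rep(seq_len(d[3]), each = d[1] * d[2]),
      value = as.vector(r$data))
  })
  data_path <- file.path(dir, "cohort_long.csv")
  manifest_path <- file.path(dir, "manifest.csv")
  data.table::fwrite(data.table::rbindlist(tabs), data_path)
  data.table::fwrite(cohort$labels, manifest_path)
  invisible(list(data = data_path, manifest = manifest_path))
}

#' Read a long-format cohort CSV back into recordings
#'
#' @param dir Directory holding `cohort_long.csv` and `manifest.csv`.
#' @param fs Sampling rate, Hz.
#' @param t0 Stimulus-onset sample index.
#' @return An `erp_cohort`-shaped list (`recordings`, `labels`).
#' @export
read_cohort_csv <- function(dir, fs = 500, t0 = 101L) {
  dt <- data.table::fread(file.path(dir, "cohort_long.csv"))
  labels <- as.data.frame(data.table::fread(file.path(dir, "manifest.csv")))
  recs <- list()
  for (key in split(seq_len(nrow(dt)),
                    paste(dt$subject, dt$condition, sep = "\r"))) {
    sub <- dt[key]
    d <- c(max(sub$trial), max(sub$channel), max(sub$sample))
    a <- array(0, d)
    a[cbind(sub$trial, sub$channel, sub$sample)] <- sub$value
    recs[[length(recs) + 1L]] <-
      epoched_recording(sub$subject[1], sub$condition[1], a, fs, t0)
  }
  structure(list(recordings = recs, labels = labels), class = "erp_cohort")
}

#' Write an ERP waveform as a channels x samples CSV
#'
#' First column `channel`, remaining columns `t<ms>` per sample.
#'
#' @param erp An `erp_waveform`.
#' @param path Output file.
#' @export
write_erp_csv <- function(erp, path) {
  t_ms <- (seq_len(ncol(erp$data)) - erp$t0) / erp$fs * 1000
  dt <- data.table::data.table(channel = seq_len(nrow(erp$data)))
  m <- data.table::as.data.table(erp$data)
  data.table::setnames(m, sprintf("t%g", t_ms))
  data.table::fwrite(cbind(dt, m), path)
  invisible(path)
}

#' Read an ERP waveform from CSV
#'
#' @param path File from [write_erp_csv()].
#' @param subject_id,condition,fs,t0 Metadata to attach.
#' @return An `erp_waveform`.
#' @export
read_erp_csv <- function(path, subject_id = NA, condition = NA,
                         fs = 500, t0 = 101L) {
  dt <- data.table::fread(path)
  structure(list(subject_id = subject_id, condition = condition,
                 data = as.matrix(dt[, -1]), fs = fs, t0 = as.integer(t0)),
            class = "erp_waveform")
}

#' Write an IMF decomposition as CSV
#'
#' Columns `imf1..imfn` and `residual`, one row per sample.
#'
#' @param dec An `imf_decomposition`.
#' @param path Output file.
#' @export
write_decomposition_csv <- function(dec, path) {
  cols <- c(stats::setNames(dec$imfs,
                            sprintf("imf%d", seq_along(dec$imfs))),
            list(residual = dec$residual))
  data.table::fwrite(data.table::as.data.table(cols), path)
  invisible(path)
}

#' Write / read a cohort-level feature table
#'
#' One row per subject: `subject_id`, `group`, then the 108 feature columns
#' in canonical order.
#'
#' @param features The `features` data.frame of a `cohort_features` object.
#' @param path CSV path.
#' @export
write_feature_csv <- function(features, path) {
  data.table::fwrite(features, path)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  as.data.frame(data.table::fread(path), check.names = FALSE)
}

#' Write a feature ranking as CSV
#'
#' Columns rank, weight, and the parsed (condition, imf, feature) triple —
#' the layout of a ranked predictor-importance table.
#'
#' @param ranking A `feature_ranking`.
#' @param path CSV path.
#' @export
write_ranking_csv <- function(ranking, path) {
  data.table::fwrite(ranking$table, path)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report` or `resampled_report`.
#' @param path JSON path.
#' @export
write_report_json <- function(report, path) {
  x <- list(classifier = report$classifier,
            accuracy = report$accuracy, sensitivity = report$sensitivity,
            specificity = report$specificity)
  if (inherits(report, "evaluation_report")) {
    x$confusion <- report$confusion
    x$folds <- lapply(report$folds, function(f)
      list(hyperparameters = f$hyperparameters,
           selected_features = f$selected_features,
           predictions = f$predictions, truth = f$truth))
  } else {
    x$resamples <- lapply(report$reports, function(r)
      list(resample_id = r$resample_id, accuracy = r$accuracy,
           sensitivity = r$sensitivity, specificity = r$specificity))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
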