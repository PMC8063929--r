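#' Run the full feature-extraction pipeline over a synthetic cohort
#'
#' Streams the cohort one recording at a time: generate epoched trials,
#' re-reference to the average, baseline-correct, average into the ERP,
#' decompose every channel into IMFs 1..3, extract the six-feature battery,
#' and reduce by the maximum across channels. Subjects failing the
#' trial-count rule (any condition below `min_trials`) and, optionally,
#' high-risk subjects with unknown diagnostic outcome are excluded; their
#' recordings are generated (keeping the RNG stream identical to
#' [generate_cohort()]) but not decomposed.
#'
#' @param spec A [cohort_spec()].
#' @param config A [sift_config()].
#' @param min_trials Exclusion threshold on trials per condition.
#' @param drop_unknown_outcome Drop subjects with `outcome_known = FALSE`.
#' @return Object of class `cohort_features`: `features` (data.frame:
#'   `subject_id`, `group`, then 108 feature columns) for retained
#'   subjects, `labels` (all subjects), `trial_counts`, `exclusions`
#'   (`low_trial`, `unknown_outcome`, `log`), `n_retained`, and
#'   `n_observations` (condition-level inputs = retained subjects x 6).
#' @export
run_cohort_pipeline <- function(spec, config = sift_config(),
                                min_trials = 10L,
                                drop_unknown_outcome = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  env <- new.env()
  env$decomps <- list()   # subject -> condition -> list of channel decomps
  env$counts <- list()
  sink <- function(rec, lab) {
    sid <- rec$subject_id
    env$counts[[sid]] <- c(env$counts[[sid]],
                           stats::setNames(dim(rec$data)[1], rec$condition))
    skip <- (drop_unknown_outcome && !lab$outcome_known) ||
      dim(rec$data)[1] < min_trials ||
      any(env$counts[[sid]] < min_trials)
    if (skip) {
      env$decomps[[sid]] <- NULL
      return(invisible())
    }
    if (!any(env$counts[[sid]] < min_trials)) {
      erp <- epochs_to_erp(rec)
      env$decomps[[sid]][[rec$condition]] <- decompose_erp(erp, config)
    }
  }
  labels <- stream_cohort(spec, sink)
  trial_counts <- do.call(rbind, lapply(names(env$counts), function(sid)
    data.frame(subject_id = sid, condition = names(env$counts[[sid]]),
               n_trials = as.integer(env$counts[[sid]]),
               stringsAsFactors = FALSE)))
  rownames(trial_counts) <- NULL
  low_log <- trial_counts[trial_counts$n_trials < min_trials, , drop = FALSE]
  rownames(low_log) <- NULL
  low_ids <- unique(low_log$subject_id)
  unk_ids <- if (drop_unknown_outcome)
    labels$subject_id[!labels$outcome_known] else character(0)
  keep <- labels$subject_id[!(labels$subject_id %in% c(low_ids, unk_ids))]
  # a subject skipped early may have a partial decomposition set; drop those
  complete <- vapply(keep, function(sid)
    length(env$decomps[[sid]]) == length(spec$conditions), TRUE)
  keep <- keep[complete]
  rows <- lapply(keep, function(sid) {
    fm <- assemble_features(env$decomps[[sid]], spec$conditions,
                            config$n_imfs, subject_id = sid)
    reduce_max_across_channels(fm)$values
  })
  features <- data.frame(subject_id = keep,
                         group = labels$group[match(keep, labels$subject_id)],
                         stringsAsFactors = FALSE, check.names = FALSE)
  features <- cbind(features, as.data.frame(do.call(rbind, rows),
                                            check.names = FALSE))
  rownames(features) <- NULL
  structure(list(features = features, labels = labels,
                 trial_counts = trial_counts,
                 exclusions = list(low_trial = low_ids,
                                   unknown_outcome = unk_ids, log = low_log),
                 n_retained = length(keep),
                 n_observations = length(keep) * length(spec$conditions)),
            class = "cohort_features")
}

#' @export
print.cohort_features <- function(x, ...) {
  cat(sprintf("Cohort features: %d subjects retained of %d (%d condition-level observations)\n",
              x$n_retained, nrow(x$labels), x$n_observations))
  if (length(x$exclusions$low_trial))
    cat("  excluded (low trials): ",
        paste(x$exclusions$low_trial, collapse = ", "), "\n")
  if (length(x$exclusions$unknown_outcome))
    cat("  excluded (unknown outcome): ",
        paste(x$exclusions$unknown_outcome, collapse = ", "), "\n")
  invisible(x)
}

#' Select feature columns for an ablation run
#'
#' `"all"` keeps all 108 columns; a condition name keeps that condition's
#' 18 columns (3 IMFs x 6 features); `"imf1"`/`"imf2"`/`"imf3"` keeps that
#' IMF's 36 columns (6 conditions x 6 features).
#'
#' @param feature_names Character vector of canonical feature labels.
#' @param subset `"all"`, a condition name, or `"imf<j>"`.
#' @return Character vector of selected column names.
#' @export
ablation_columns <- function(feature_names, subset = "all") {
  if (identical(subset, "all")) return(feature_names)
  info <- parse_feature_labels(feature_names)
  if (subset %in% erp_conditions())
    return(feature_names[info$condition == subset])
  if (grepl("^imf[0-9]+$", subset))
    return(feature_names[info$imf == as.integer(sub("imf", "", subset))])
  stop("unknown ablation subset: ", subset)
}

#' Run a classification experiment on a cohort feature table
#'
#' The risk problem classifies control vs high-risk (HR-noASD and HR-ASD
#' pooled; positive class HR) in a single nested-CV run (default 10 outer x
#' 9 inner folds). The outcome problem classifies HR-ASD vs HR-noASD
#' (positive class HR-ASD) over balanced resamples of the majority class
#' (default 5 repeats, 5 outer x 4 inner folds each), reporting per-resample
#' metrics and their unweighted mean. Ablations restrict the feature columns
#' to one condition (18 features) or one IMF (36 features).
#'
#' @param cohort A `cohort_features` object or its `features` data.frame.
#' @param problem `"risk"` or `"outcome"`.
#' @param classifier `"knn"` or `"svm"`.
#' @param config A [cv_config()]; defaults follow the problem's design
#'   (10x9 or 5x4).
#' @param subset Ablation selector, see [ablation_columns()].
#' @param resamples Balanced-resample count for the outcome problem.
#' @return For `"risk"`, an `evaluation_report`. For `"outcome"`, an object
#'   of class `resampled_report`: per-resample reports plus mean metrics.
#' @export
run_experiment <- function(cohort, problem = c("risk", "outcome"),
                           classifier = c("knn", "svm"), config = NULL,
                           subset = "all", resamples = 5L) {
  problem <- match.arg(problem)
  classifier <- match.arg(classifier)
  features <- if (inherits(cohort, "cohort_features")) cohort$features
              else cohort
  stopifnot(all(c("subject_id", "group") %in% names(features)))
  fcols <- setdiff(names(features), c("subject_id", "group"))
  fcols <- ablation_columns(fcols, subset)
  x <- as.matrix(features[, fcols, drop = FALSE])
  rownames(x) <- features$subject_id
  if (is.null(config)) {
    config <- if (problem == "risk") cv_config(10L, 9L)
              else cv_config(5L, 4L)
  }
  if (problem == "risk") {
    y <- ifelse(features$group == "control", "control", "HR")
    return(nested_cv(x, y, classifier, config, positive_class = "HR"))
  }
  hr <- features$group %in% c("HR-ASD", "HR-noASD")
  ids_asd <- features$subject_id[features$group == "HR-ASD"]
  ids_no <- features$subject_id[features$group == "HR-noASD"]
  sets <- balanced_resample(ids_asd, ids_no, repeats = resamples,
                            seed = config$seed)
  reports <- lapply(seq_along(sets), function(i) {
    idx <- match(sets[[i]], features$subject_id)
    cfg <- config
    cfg$seed <- config$seed + i
    r <- nested_cv(x[idx, , drop = FALSE], features$group[idx], classifier,
                   cfg, positive_class = "HR-ASD")
    r$resample_id <- i
    r
  })
  mean_of <- function(field) mean(vapply(reports, `[[`, 0, field), na.rm = TRUE)
  structure(list(reports = reports,
                 accuracy = mean_of("accuracy"),
                 sensitivity = mean_of("sensitivity"),
                 specificity = mean_of("specificity"),
                 resamples = length(reports), classifier = classifier),
            class = "resampled_report")
}

#' @export
print.resampled_report <- function(x, ...) {
  cat(sprintf("Balanced-resample evaluation (%s, %d resamples)\n",
              x$classifier, x$resamples))
  cat(sprintf("  mean accuracy %.4f | sensitivity %.4f | specificity %.4f\n",
              x$accuracy, x$sensitivity, x$specificity))
  for (r in x$reports)
    cat(sprintf("  resample %d: accuracy %.4f\n", r$resample_id, r$accuracy))
  invisible(x)
}

#' Performance table across ablation runs
#'
#' Runs one experiment per row of the study's comparison table: each
#' condition separately (18 features), each IMF separately (36 features),
#' and all features with in-fold weight-correlation selection.
#'
#' @param cohort A `cohort_features` object.
#' @param problem,classifier As in [run_experiment()].
#' @param selection_k Features kept in the all-features run.
#' @param seed Seed passed to each run's [cv_config()].
#' @return data.frame: subset, n_features, accuracy, sensitivity,
#'   specificity.
#' @export
performance_table <- function(cohort, problem = "risk", classifier = "knn",
                              selection_k = 11L, seed = 1L) {
  subsets <- c(erp_conditions(), "imf1", "imf2", "imf3", "all")
  rows <- lapply(subsets, function(s) {
    base <- if (problem == "risk") cv_config(10L, 9L, seed = seed)
            else cv_config(5L, 4L, seed = seed)
    if (s == "all") base$selection_k <- selection_k
    r <- run_experiment(cohort, problem, classifier, config = base,
                        subset = s)
    nf <- if (s == "all") selection_k
          else length(ablation_columns(feature_labels(), s))
    data.frame(subset = s, n_features = nf,
               accuracy = r$accuracy, sensitivity = r$sensitivity,
               specificity = r$specificity)
  })
  do.call(rbind, rows)
}
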