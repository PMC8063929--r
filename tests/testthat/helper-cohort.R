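# shared small fixtures, generated once per test run

.fixtures <- new.env()

# tiny materialized cohort: 2/2/2 subjects, 4 channels, ~12 trials
small_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(small_spec())
  }
  .fixtures$cohort
}

small_spec <- function(...) {
  args <- list(n_control = 2L, n_hr_noasd = 2L, n_hr_asd = 2L,
               n_channels = 4L, trials_mean = 12, seed = 101L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_spec, args)
}

# pipeline features for a slightly larger cohort used by classifier tests
small_features <- function() {
  if (is.null(.fixtures$features)) {
    spec <- cohort_spec(n_control = 8L, n_hr_noasd = 5L, n_hr_asd = 3L,
                        n_channels = 6L, trials_mean = 20, seed = 202L)
    .fixtures$features <- run_cohort_pipeline(spec)
  }
  .fixtures$features
}

# two-tone battery matching the frozen reference decompositions
reference_battery <- function() {
  t <- (0:499) / 500
  list(two_tone_40_5 = sin(2 * pi * 40 * t) + sin(2 * pi * 5 * t),
       two_tone_60_8 = 0.7 * sin(2 * pi * 60 * t) +
         1.5 * sin(2 * pi * 8 * t + 1),
       two_tone_25_3 = 2.0 * sin(2 * pi * 25 * t + 0.5) +
         sin(2 * pi * 3 * t))
}

# build an epoched_recording with given per-condition trial counts from a
# deterministic ramp (content irrelevant to exclusion logic)
fake_recordings <- function(counts_by_subject,
                            conditions = erp_conditions()) {
  recs <- list()
  for (sid in names(counts_by_subject)) {
    counts <- counts_by_subject[[sid]]
    for (ci in seq_along(conditions)) {
      a <- array(seq_len(counts[ci] * 2 * 10), c(counts[ci], 2, 10))
      recs[[length(recs) + 1L]] <-
        epoched_recording(sid, conditions[ci], a, fs = 500, t0 = 5L)
    }
  }
  recs
}
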