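#' Stimulus conditions of the infant face/gaze paradigm
#'
#' Six visual conditions: dynamic gaze shifts (direct, averted), static gaze
#' (direct, averted), any face, and a visual-noise control that contains no
#' face. Order is fixed and defines feature-column order downstream.
#' @export
erp_conditions <- function() {
  c("direct_gaze", "averted_gaze", "static_direct", "static_averted",
    "face", "noise")
}

#' Group labels of the cohort
#' @export
erp_groups <- function() c("control", "HR-noASD", "HR-ASD")

# per-condition gain on the face-evoked components; the noise condition
# carries no face components at all
condition_gains <- c(direct_gaze = 1.10, averted_gaze = 1.00,
                     static_direct = 0.95, static_averted = 0.90,
                     face = 1.05, noise = 0.00)

#' Group-effect specification for the synthetic ERP generator
#'
#' Describes the deterministic ERP morphology (P100, N290, P400 as Gaussian
#' bumps in time with occipitally weighted channel profiles), how the
#' high-risk groups differ from controls (later N290/P400 peaks, scaled
#' component amplitudes, elevated beta/gamma burst power), and the
#' oscillatory bands.
#'
#' Two presets are provided: `"strong"` (group effects large enough to make
#' the groups separable after feature extraction) and `"null"` (all group
#' effects switched off — identical generating distribution in every group,
#' so any classifier must perform at chance).
#'
#' @param preset `"strong"` or `"null"`.
#' @param group_latency_shift Milliseconds added to the N290 and P400 peak
#'   latencies for high-risk subjects.
#' @param group_amplitude_scale Named multiplicative factor on all component
#'   amplitudes per group (`control`, `HR-noASD`, `HR-ASD`).
#' @param osc_power Matrix (bands x groups) of oscillatory burst amplitudes
#'   in microvolts; rows `beta`, `gamma`; columns the three groups.
#' @param component_params Data frame with columns `component`, `latency_ms`,
#'   `amplitude_uv`, `width_ms`, `topo_center`, `topo_width` (the last two as
#'   fractions of the channel axis).
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(preset = c("strong", "null"),
                        group_latency_shift = NULL,
                        group_amplitude_scale = NULL,
                        osc_power = NULL,
                        component_params = NULL) {
  preset <- match.arg(preset)
  if (is.null(component_params)) {
    component_params <- data.frame(
      component = c("P100", "N290", "P400"),
      latency_ms = c(100, 290, 400),
      amplitude_uv = c(6, -8, 10),
      width_ms = c(25, 40, 60),
      topo_center = c(0.78, 0.72, 0.66),
      topo_width = c(0.12, 0.12, 0.12))
  }
  groups <- erp_groups()
  if (preset == "strong") {
    if (is.null(group_latency_shift)) group_latency_shift <- 40
    if (is.null(group_amplitude_scale))
      group_amplitude_scale <- c(1.0, 0.6, 0.45)
    if (is.null(osc_power))
      osc_power <- rbind(beta = c(0.5, 5.0, 6.5),
                         gamma = c(0.3, 4.5, 6.0))
  } else {
    if (is.null(group_latency_shift)) group_latency_shift <- 0
    if (is.null(group_amplitude_scale)) group_amplitude_scale <- c(1, 1, 1)
    if (is.null(osc_power))
      osc_power <- rbind(beta = c(0.5, 0.5, 0.5),
                         gamma = c(0.3, 0.3, 0.3))
  }
  names(group_amplitude_scale) <- groups
  colnames(osc_power) <- groups
  stopifnot(all(component_params$width_ms > 0),
            all(osc_power >= 0),
            all(component_params$topo_center >= 0 &
                  component_params$topo_center <= 1))
  structure(list(component_params = component_params,
                 group_latency_shift = group_latency_shift,
                 group_amplitude_scale = group_amplitude_scale,
                 osc_bands = data.frame(band = c("beta", "gamma"),
                                        f_lo = c(13, 30), f_hi = c(30, 60)),
                 osc_power = osc_power,
                 osc_topo = c(center = 0.70, width = 0.20),
                 preset = preset),
            class = "effect_spec")
}

#' Cohort specification for the synthetic ERP generator
#'
#' Mirrors the sibling-risk study design: three groups (control, HR-noASD,
#' HR-ASD), six stimulus conditions, 128-channel EEG at 500 Hz, epochs of
#' \[-200, 800) ms around stimulus onset. Extra subjects can be added to
#' exercise the exclusion rules: `n_low_trial` subjects are forced below 10
#' trials in one condition, and `n_missing_outcome` high-risk subjects carry
#' no diagnostic-outcome label.
#'
#' @param n_control,n_hr_noasd,n_hr_asd Group sizes (defaults 44/33/17).
#' @param n_channels Number of EEG channels (default 128).
#' @param fs Sampling rate, Hz (default 500).
#' @param epoch_window Epoch limits in ms, half-open `[from, to)`.
#' @param conditions Six unique condition names.
#' @param trials_mean Expected retained trials per subject and condition
#'   (Poisson, floored at 1).
#' @param p_low_trials Probability that a subject x condition is forced
#'   below 10 trials.
#' @param effect An [effect_spec()].
#' @param noise_sd Trial background-noise scale in microvolts (1/f component
#'   at this SD plus white noise at half of it).
#' @param seed Integer RNG seed; identical spec + seed is bit-reproducible.
#' @param n_low_trial Extra subjects (group assigned round-robin) forced to
#'   have fewer than 10 trials in one condition.
#' @param n_missing_outcome Extra high-risk subjects with unknown diagnostic
#'   outcome (`outcome_known = FALSE`).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 44L, n_hr_noasd = 33L, n_hr_asd = 17L,
                        n_channels = 128L, fs = 500,
                        epoch_window = c(-200, 800),
                        conditions = erp_conditions(),
                        trials_mean = 30, p_low_trials = 0,
                        effect = effect_spec("strong"), noise_sd = 5,
                        seed = 1L, n_low_trial = 0L,
                        n_missing_outcome = 0L) {
  if (n_channels < 1) stop("invalid cohort spec: n_channels must be >= 1")
  if (fs <= 0) stop("invalid cohort spec: fs must be > 0")
  n_samples <- diff(epoch_window) / 1000 * fs
  if (abs(n_samples - round(n_samples)) > 1e-9)
    stop("invalid cohort spec: epoch_window span must be a whole number of samples at fs")
  if (length(conditions) != 6L || anyDuplicated(conditions))
    stop("invalid cohort spec: conditions must be 6 unique names")
  if (p_low_trials < 0 || p_low_trials > 1)
    stop("invalid cohort spec: p_low_trials must be in [0, 1]")
  if (noise_sd < 0) stop("invalid cohort spec: noise_sd must be >= 0")
  if (!inherits(effect, "effect_spec"))
    stop("invalid cohort spec: effect must be an effect_spec")
  structure(list(n_control = as.integer(n_control),
                 n_hr_noasd = as.integer(n_hr_noasd),
                 n_hr_asd = as.integer(n_hr_asd),
                 n_channels = as.integer(n_channels), fs = fs,
                 epoch_window = epoch_window,
                 n_samples = as.integer(round(n_samples)),
                 t0 = as.integer(round(-epoch_window[1] / 1000 * fs)) + 1L,
                 conditions = conditions, trials_mean = trials_mean,
                 p_low_trials = p_low_trials, effect = effect,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 n_low_trial = as.integer(n_low_trial),
                 n_missing_outcome = as.integer(n_missing_outcome)),
            class = "cohort_spec")
}

# evaluate a block with a local RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# smooth unimodal channel-weight profile in [0, 1], peaked at `center`
# (fraction of the channel axis)
channel_topography <- function(n_channels, center, width) {
  if (n_channels == 1L) return(1)
  i <- seq(0, 1, length.out = n_channels)
  exp(-(i - center)^2 / (2 * width^2))
}

# map auxiliary labels onto generating parameters; HR subjects with unknown
# outcome are generated as HR-noASD
generating_group <- function(group) {
  ifelse(group == "HR-unknown", "HR-noASD", group)
}

#' Deterministic (noise-free) ERP template for one group and condition
#'
#' The sum of the Gaussian-shaped P100/N290/P400 components with the group's
#' latency shift (N290/P400 only) and amplitude scale applied, each spread
#' over channels by its topography profile. The noise condition has no face
#' components and returns zeros.
#'
#' @param effect An [effect_spec()].
#' @param group One of `erp_groups()` (or `"HR-unknown"`).
#' @param condition Condition name.
#' @param n_channels,fs,n_samples,t0 Geometry of the epoch.
#' @return `n_channels x n_samples` matrix in microvolts.
#' @export
erp_template <- function(effect, group, condition, n_channels,
                         fs = 500, n_samples = 500L, t0 = 101L) {
  condition <- match.arg(condition, erp_conditions())
  group <- generating_group(group)
  group <- match.arg(group, erp_groups())
  t_ms <- (seq_len(n_samples) - t0) / fs * 1000
  out <- matrix(0, n_channels, n_samples)
  gain <- condition_gains[[condition]]
  if (gain == 0) return(out)
  amp_scale <- effect$group_amplitude_scale[[group]]
  shift <- if (group == "control") 0 else effect$group_latency_shift
  cp <- effect$component_params
  for (j in seq_len(nrow(cp))) {
    lat <- cp$latency_ms[j] + if (cp$component[j] == "P100") 0 else shift
    bump <- cp$amplitude_uv[j] * amp_scale * gain *
      exp(-(t_ms - lat)^2 / (2 * cp$width_ms[j]^2))
    topo <- channel_topography(n_channels, cp$topo_center[j], cp$topo_width[j])
    out <- out + tcrossprod(topo, bump)
  }
  out
}

# 1/f-amplitude-weighted ("pink") noise, channels x samples, unit variance
# in expectation; consumes RNG
pink_noise <- function(n_channels, n_samples) {
  w <- matrix(stats::rnorm(n_samples * n_channels), n_samples, n_channels)
  sp <- stats::mvfft(w)
  k <- c(0, pmin(1:(n_samples - 1), (n_samples - 1):1))
  wt <- c(0, 1 / sqrt(k[-1]))
  wt <- wt / sqrt(mean(wt^2))
  t(Re(stats::mvfft(sp * wt, inverse = TRUE)) / n_samples)
}

# one Hann-windowed band-limited burst per oscillatory band, phase-locked to
# stimulus onset (evoked oscillation: narrow frequency, phase and latency
# jitter across trials, so the burst survives trial averaging); consumes RNG
osc_bursts <- function(effect, group, n_channels, fs, n_samples, t0) {
  group <- generating_group(group)
  out <- matrix(0, n_channels, n_samples)
  topo <- channel_topography(n_channels, effect$osc_topo[["center"]],
                             effect$osc_topo[["width"]])
  t_s <- (seq_len(n_samples) - t0) / fs
  for (b in seq_len(nrow(effect$osc_bands))) {
    fc <- (effect$osc_bands$f_lo[b] + effect$osc_bands$f_hi[b]) / 2
    f <- stats::runif(1, fc - 2, fc + 2)
    phase <- stats::rnorm(1, 0, 0.2)
    c0 <- 0.25                                 # s, nominal burst latency
    center <- c0 + stats::rnorm(1, 0, 0.01)    # envelope latency jitter
    dur <- 0.15                                # s, burst length
    amp <- effect$osc_power[b, group]
    win <- ifelse(abs(t_s - center) <= dur / 2,
                  0.5 * (1 + cos(2 * pi * (t_s - center) / dur)), 0)
    # carrier referenced to the fixed nominal latency, so the oscillation is
    # phase-locked across trials and survives trial averaging
    burst <- amp * win * sin(2 * pi * f * (t_s - c0) + phase)
    out <- out + tcrossprod(topo, burst)
  }
  out
}

#' Generate one trial of synthetic epoched EEG
#'
#' One trial = deterministic component template ([erp_template()]) +
#' band-limited oscillatory bursts at group-specific power + 1/f background
#' noise + white noise. Consumes the current RNG stream; seed outside for
#' reproducibility.
#'
#' @inheritParams erp_template
#' @param noise_sd Background-noise scale, microvolts.
#' @return `n_channels x n_samples` matrix in microvolts.
#' @export
generate_trial <- function(effect, group, condition, n_channels,
                           fs = 500, n_samples = 500L, t0 = 101L,
                           noise_sd = 5) {
  det <- erp_template(effect, group, condition, n_channels, fs, n_samples, t0)
  osc <- osc_bursts(effect, group, n_channels, fs, n_samples, t0)
  bg <- if (noise_sd > 0) {
    noise_sd * pink_noise(n_channels, n_samples) +
      (noise_sd / 2) * matrix(stats::rnorm(n_channels * n_samples),
                              n_channels, n_samples)
  } else 0
  det + osc + bg
}

# subject table for a cohort spec: core groups in spec counts, then forced
# low-trial extras (groups round-robin), then HR subjects with unknown outcome
cohort_labels <- function(spec) {
  groups <- c(rep("control", spec$n_control),
              rep("HR-noASD", spec$n_hr_noasd),
              rep("HR-ASD", spec$n_hr_asd))
  extra_lt <- rep(erp_groups(), length.out = spec$n_low_trial)
  extra_mo <- rep("HR-unknown", spec$n_missing_outcome)
  all_groups <- c(groups, extra_lt, extra_mo)
  n <- length(all_groups)
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             group = all_groups,
             outcome_known = c(rep(TRUE, length(groups) + length(extra_lt)),
                               rep(FALSE, length(extra_mo))),
             forced_low_trial = c(rep(FALSE, length(groups)),
                                  rep(TRUE, length(extra_lt)),
                                  rep(FALSE, length(extra_mo))),
             stringsAsFactors = FALSE)
}

# draw trial counts per condition for one subject; consumes RNG
draw_trial_counts <- function(spec, forced_low) {
  k <- length(spec$conditions)
  n <- pmax(1L, stats::rpois(k, spec$trials_mean))
  low <- stats::runif(k) < spec$p_low_trials
  if (forced_low) low[sample.int(k, 1L)] <- TRUE
  n[low] <- sample(1:9, sum(low), replace = TRUE)
  n
}

# core generator: iterates subject-major / condition-minor under the spec
# seed and hands each epoched recording to `sink(recording, label_row)`;
# both the materializing and the streaming entry points share this loop, so
# a given spec + seed yields bit-identical data on either path
stream_cohort <- function(spec, sink) {
  labels <- cohort_labels(spec)
  with_seed(spec$seed, {
    for (s in seq_len(nrow(labels))) {
      counts <- draw_trial_counts(spec, labels$forced_low_trial[s])
      for (ci in seq_along(spec$conditions)) {
        nt <- counts[ci]
        dat <- array(0, dim = c(nt, spec$n_channels, spec$n_samples))
        for (tr in seq_len(nt)) {
          dat[tr, , ] <- generate_trial(spec$effect, labels$group[s],
                                        spec$conditions[ci], spec$n_channels,
                                        spec$fs, spec$n_samples, spec$t0,
                                        spec$noise_sd)
        }
        rec <- epoched_recording(labels$subject_id[s], spec$conditions[ci],
                                 dat, spec$fs, spec$t0)
        sink(rec, labels[s, ])
      }
    }
  })
  labels
}

#' Construct an epoched recording
#'
#' @param subject_id Subject identifier.
#' @param condition Condition name.
#' @param data `trials x channels x samples` array, microvolts.
#' @param fs Sampling rate, Hz.
#' @param t0 1-based sample index of stimulus onset.
#' @return Object of class `epoched_recording`.
#' @export
epoched_recording <- function(subject_id, condition, data, fs, t0) {
  stopifnot(length(dim(data)) == 3L, all(is.finite(data)))
  structure(list(subject_id = subject_id, condition = condition,
                 data = data, fs = fs, t0 = as.integer(t0)),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoched recording %s / %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$condition, d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Generate a full synthetic cohort in memory
#'
#' Returns every trial of every subject x condition. Memory grows as
#' subjects x conditions x trials x channels x samples; for study-size
#' cohorts at 128 channels prefer the streaming pipeline
#' ([run_cohort_pipeline()]), which never holds more than one recording.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `erp_cohort`: list with `recordings` (list of
#'   [epoched_recording()]s), `labels` (subject table with `group`,
#'   `outcome_known`, `forced_low_trial`), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  recs <- vector("list", 0L)
  labels <- stream_cohort(spec, function(rec, lab) {
    recs[[length(recs) + 1L]] <<- rec
  })
  structure(list(recordings = recs, labels = labels, spec = spec),
            class = "erp_cohort")
}

#' @export
print.erp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ERP cohort: %d subjects x %d conditions (%d recordings), %d channels @ %g Hz\n",
              nrow(x$labels), length(x$spec$conditions),
              length(x$recordings), x$spec$n_channels, x$spec$fs))
  print(table(x$labels$group))
  invisible(x)
}
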