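#' Draw a subject's per-round severity trajectory
#'
#' Round 1 is always the medication-OFF baseline `s_off`. Later rounds sit
#' near the subject's ON-state severity `s_on < s_off` with small integer
#' jitter; with probability `wearoff_prob` the final round reverts towards
#' the OFF baseline (medication wearing off before the next dose). Scores
#' are integers clamped to the configured OFF/ON ranges.
#'
#' @param profile list with `s_off`, `s_on` (integers, `s_on < s_off`).
#' @param n_rounds number of assessment rounds (>= 2).
#' @param config a [cohort_config()].
#' @return data.frame with columns `round`, `severity`, `med_state`.
#' @export
severity_trajectory <- function(profile, n_rounds, config = cohort_config()) {
  stopifnot(n_rounds >= 2)
  lo <- min(config$severity_on_range[1], config$severity_off_range[1])
  hi <- config$severity_off_range[2]
  sev <- integer(n_rounds); med <- character(n_rounds)
  sev[1] <- profile$s_off; med[1] <- "OFF"
  for (r in 2:n_rounds) {
    sev[r] <- as.integer(round(profile$s_on + stats::rnorm(1, 0, 2)))
    med[r] <- "ON"
  }
  if (n_rounds >= 3 && stats::runif(1) < config$wearoff_prob) {
    sev[n_rounds] <- as.integer(round(profile$s_off - abs(stats::rnorm(1, 2, 1))))
    med[n_rounds] <- "OFF"
  }
  # ON rounds stay strictly below the subject's OFF baseline
  on <- med == "ON"
  sev[on] <- pmin(sev[on], profile$s_off - 1L)
  sev <- pmax(pmin(sev, hi), lo)
  data.frame(round = seq_len(n_rounds), severity = as.integer(sev),
             med_state = med, stringsAsFactors = FALSE)
}

#' Synthesize one 5 s gyroscope window at a given severity
#'
#' Per channel, the signal is `movement + tremor + noise`:
#' * movement: a band-limited (0.5-3 Hz by default) random oscillation whose
#'   amplitude `A0 * (1 - brady_slope * severity / 60)` decreases
#'   monotonically with severity (bradykinesia), scaled by the activity
#'   (resting 0.2x, ambulation 1.5x, other ADLs 1x);
#' * tremor: an amplitude-modulated sinusoid at a frequency drawn uniformly
#'   from 4-6 Hz with amplitude
#'   `tremor_amp_coeff * max(0, severity - tremor_onset) / 60`, carried at
#'   twice the amplitude on the wrist channels (resting-tremor predominance);
#' * noise: additive Gaussian with SD `noise_sigma`.
#'
#' @param severity UPDRS-III-like severity in `[0, 108]`.
#' @param activity activity label (scales movement amplitude).
#' @param config a [cohort_config()].
#' @param n_samples window length in samples.
#' @return Numeric matrix `n_samples x 6` (deg/s).
#' @export
synth_window <- function(severity, activity = "ambulation",
                         config = cohort_config(), n_samples = 320L) {
  stopifnot(severity >= 0, severity <= 108)
  fs <- config$fs
  t <- (seq_len(n_samples) - 1) / fs
  act_scale <- switch(activity, resting = 0.2, ambulation = 1.5,
                      `watching television` = 0.3, snacking = 0.5,
                      `desk work` = 0.5, 1)
  a_m <- config$movement_amp * max(0, 1 - config$brady_slope * severity / 60) *
    act_scale
  a_t <- config$tremor_amp_coeff *
    max(0, severity - config$tremor_onset) / 60
  out <- matrix(0, n_samples, 6)
  for (ch in 1:6) {
    # voluntary movement: a few random tones inside the movement band
    mov <- numeric(n_samples)
    for (k in 1:3) {
      f <- stats::runif(1, config$movement_band[1], config$movement_band[2])
      mov <- mov + sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
    mov <- a_m * mov / 3
    # tremor: slow random amplitude modulation around a 4-6 Hz carrier
    f_tr <- stats::runif(1, config$tremor_f_range[1], config$tremor_f_range[2])
    am <- 1 + 0.3 * sin(2 * pi * stats::runif(1, 0.1, 0.5) * t +
                          stats::runif(1, 0, 2 * pi))
    site_gain <- if (ch <= 3) 1 else 0.5  # wrist carries 2x the ankle tremor
    tre <- a_t * site_gain * am * sin(2 * pi * f_tr * t + stats::runif(1, 0, 2 * pi))
    out[, ch] <- mov + tre + stats::rnorm(n_samples, 0, config$noise_sigma)
  }
  out
}

# Build the continuous trace for one activity interval by tiling 5 s blocks.
synth_interval <- function(duration_s, severity, activity, config) {
  n <- as.integer(round(duration_s * config$fs))
  blocks <- ceiling(n / 320L)
  sig <- do.call(rbind, lapply(seq_len(blocks), function(i)
    synth_window(severity, activity, config)))
  sig[seq_len(n), , drop = FALSE]
}

# Partition a round (after the exam) into labelled activity intervals.
draw_activities <- function(t0, t1, labels, min_s = 15, max_s = 60) {
  min_s <- min(min_s, t1 - t0)
  max_s <- max(min_s, max_s)
  acts <- list(); t <- t0
  while (t1 - t >= min_s) {
    d <- min(stats::runif(1, min_s, max_s), t1 - t)
    acts[[length(acts) + 1L]] <- list(label = sample(labels, 1),
                                      start_s = t, end_s = t + d)
    t <- t + d
  }
  if (t < t1 && length(acts) > 0) acts[[length(acts)]]$end_s <- t1
  acts
}

simulate_subject_a <- function(id, profile, config) {
  n_rounds <- 4L
  traj <- severity_trajectory(profile, n_rounds, config)
  fs <- config$fs
  rounds <- list(); exclusions <- list(); segs <- list()
  for (r in seq_len(n_rounds)) {
    r0 <- (r - 1) * config$round_duration_s
    r1 <- r * config$round_duration_s
    act_start <- r0 + config$exam_s
    if (config$exam_s > 0)
      exclusions[[length(exclusions) + 1L]] <- c(r0, act_start)
    acts <- draw_activities(act_start, r1, config$activities)
    sev <- traj$severity[r]
    # exam segment is generated too (it is excluded downstream, not absent)
    if (config$exam_s > 0)
      segs[[length(segs) + 1L]] <- synth_interval(config$exam_s, sev,
                                                  "ambulation", config)
    for (a in acts)
      segs[[length(segs) + 1L]] <- synth_interval(a$end_s - a$start_s, sev,
                                                  a$label, config)
    covered <- if (length(acts)) acts[[length(acts)]]$end_s else act_start
    if (r1 - covered > 1e-9)
      segs[[length(segs) + 1L]] <- synth_interval(r1 - covered, sev,
                                                  "resting", config)
    rounds[[r]] <- list(index = r, start_s = r0, end_s = r1, updrs = sev,
                        med_state = traj$med_state[r], activities = acts)
  }
  data <- do.call(rbind, segs)
  data <- data[seq_len(n_rounds * config$round_duration_s * fs), , drop = FALSE]
  sensor_recording(id, data, fs = fs, rounds = rounds, exclusions = exclusions)
}

simulate_subject_b <- function(id, profile, config) {
  traj <- severity_trajectory(profile, 2L, config)
  fs <- config$fs
  half <- config$session_duration_s / 2
  rounds <- list(); exclusions <- list(); segs <- list()
  for (r in 1:2) {
    r0 <- (r - 1) * half; r1 <- r * half
    act_start <- r0 + config$exam_s
    if (config$exam_s > 0) {
      exclusions[[length(exclusions) + 1L]] <- c(r0, act_start)
      segs[[length(segs) + 1L]] <- synth_interval(config$exam_s,
                                                  traj$severity[r],
                                                  "ambulation", config)
    }
    acts <- draw_activities(act_start, r1, config$activities_b,
                            min_s = min(60, r1 - act_start),
                            max_s = min(600, r1 - act_start))
    for (a in acts)
      segs[[length(segs) + 1L]] <- synth_interval(a$end_s - a$start_s,
                                                  traj$severity[r],
                                                  a$label, config)
    covered <- if (length(acts)) acts[[length(acts)]]$end_s else act_start
    if (r1 - covered > 1e-9)
      segs[[length(segs) + 1L]] <- synth_interval(r1 - covered,
                                                  traj$severity[r],
                                                  "desk work", config)
    rounds[[r]] <- list(index = r, start_s = r0, end_s = r1,
                        updrs = traj$severity[r],
                        med_state = traj$med_state[r], activities = acts)
  }
  data <- do.call(rbind, segs)
  data <- data[seq_len(config$session_duration_s * fs), , drop = FALSE]
  sensor_recording(id, data, fs = fs, rounds = rounds, exclusions = exclusions)
}

#' Simulate a synthetic Parkinson's cohort
#'
#' Generates `n_subjects` recordings split into protocol groups A (4 rounds
#' of scripted ADLs, medication OFF in round 1 then ON, optional wear-off in
#' the last round) and B (one continuous homelike session scored at start
#' and end). Every recording carries round annotations with integer
#' UPDRS-III-like scores and exam exclusion intervals, in exactly the format
#' the preprocessing stage consumes. Deterministic under `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return List of `sensor_recording` objects.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  n <- config$n_subjects
  n_a <- max(0L, min(n, as.integer(round(n * config$group_a_fraction))))
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("S%02d", i)
    s_off <- as.integer(round(stats::runif(1, config$severity_off_range[1],
                                           config$severity_off_range[2])))
    s_on <- as.integer(round(s_off * stats::runif(1, 0.35, 0.7)))
    s_on <- max(config$severity_on_range[1],
                min(s_on, config$severity_on_range[2], s_off - 1L))
    profile <- list(subject_id = id, s_off = s_off, s_on = s_on)
    recs[[i]] <- if (i <= n_a) simulate_subject_a(id, profile, config)
                 else simulate_subject_b(id, profile, config)
  }
  recs
}
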