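# Shared fixtures: everything is generated in code at test time.

# Tiny network widths used throughout the suite; published defaults are
# exercised separately by the config-integrity and shape tests.
tiny_net_config <- function(...) {
  network_config(r_filters1 = 3L, r_kernel1 = 5L, r_pool_size = 4L,
                 r_pool_stride = 2L, r_dropout1 = 0, r_filters2 = 4L,
                 r_kernel2 = 3L, r_dropout2 = 0,
                 s_filters1 = 3L, s_kernel1 = c(3L, 3L), s_pool = c(2L, 2L),
                 s_dropout1 = 0, s_filters2 = 4L, s_kernel2 = c(3L, 3L),
                 s_dropout2 = 0, task_head = 5L, lstm = 4L, lstm_dropout = 0,
                 fusion = 6L, ...)
}

tiny_input <- list(len = 20L, ch = 6L, fbins = 9L, frames = 11L)

# Reduced-width config for real training runs on synthetic cohorts.
small_net_config <- function(...) {
  network_config(r_filters1 = 8L, r_filters2 = 16L, s_filters1 = 8L,
                 s_filters2 = 16L, task_head = 32L, lstm = 16L,
                 fusion = 32L, ...)
}

# Cropped-band STFT used by the training experiments (guard band above the
# 0.5-15 Hz filter passband).
train_stft <- function() stft_config(crop_hz = 16)

# Small synthetic cohort preprocessed into a window set.
small_cohort_ws <- function(n_subjects = 4, round_s = 60, seed = 21,
                            group_a_fraction = 1, exam_s = 10,
                            session_s = 240) {
  cc <- cohort_config(n_subjects = n_subjects,
                      group_a_fraction = group_a_fraction,
                      round_duration_s = round_s,
                      session_duration_s = session_s,
                      exam_s = exam_s, seed = seed)
  preprocess_cohort(simulate_cohort(cc), stft = train_stft())
}

# A deterministic single recording with simple structure for preprocess
# tests: rounds/activities/exclusions laid out by hand.
toy_recording <- function(duration_s = 30, fs = 64, rounds = list(),
                          exclusions = list(), signal = NULL) {
  n <- duration_s * fs
  if (is.null(signal)) signal <- matrix(seq_len(n * 6) / (n * 6), n, 6)
  sensor_recording("T1", signal, fs = fs, rounds = rounds,
                   exclusions = exclusions)
}

rand_window <- function(n = 320, ch = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(n * ch), n, ch)
}
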