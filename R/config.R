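#' Short-time Fourier transform configuration
#'
#' Parameters of the per-window spectrogram. The defaults reproduce the
#' pipeline's standard configuration: a 1 s Kaiser window at 64 Hz with 90%
#' overlap. Because 0.9 of a 64-sample window is fractional (57.6 samples),
#' the overlap is realized as 58 samples, i.e. an integer hop of 6, which is
#' the closest attainable hop to the nominal overlap. With 5 s (320-sample)
#' windows this yields spectrograms of 33 frequency bins by 43 frames.
#'
#' @param win_s STFT window length in seconds.
#' @param overlap_frac nominal fractional overlap in `[0, 1)`.
#' @param kaiser_beta Kaiser window shape parameter; 8 gives roughly -58 dB
#'   sidelobes, a standard compromise between leakage and resolution.
#' @param nfft FFT length; `NULL` uses the window length in samples.
#' @param log_floor_db magnitudes are reported as `20*log10()` dB, floored at
#'   this value so silent bins are finite.
#' @param crop_hz optionally drop frequency bins above this limit. The
#'   default keeps the full one-sided band (0-32 Hz, 33 bins); cropping to
#'   e.g. 16 Hz retains the filter passband (0.5-15 Hz) plus a guard band
#'   and shrinks the spectrogram for cheaper downstream models.
#' @return A list of class `stft_config`.
#' @export
stft_config <- function(win_s = 1, overlap_frac = 0.9, kaiser_beta = 8,
                        nfft = NULL, log_floor_db = -80, crop_hz = NULL) {
  stopifnot(win_s > 0, overlap_frac >= 0, overlap_frac < 1, log_floor_db < 0)
  structure(list(win_s = win_s, overlap_frac = overlap_frac,
                 kaiser_beta = kaiser_beta, nfft = nfft,
                 log_floor_db = log_floor_db, crop_hz = crop_hz),
            class = "stft_config")
}

#' Pretext-task transformation configuration
#'
#' Controls the three self-supervised signal transformations. Rotation draws
#' an independent random 3-D rotation per sensor site (axis uniform on the
#' sphere, angle uniform in +/- `rotation_max_deg`); permutation shuffles
#' `permute_segments` contiguous blocks with a non-identity permutation; time
#' warping resamples along a smooth monotone warp built from a cubic spline
#' through `warp_knots` anchors perturbed with standard deviation
#' `warp_sigma` (as a fraction of the window duration).
#'
#' @param rotation_max_deg maximal rotation angle in degrees.
#' @param permute_segments number of blocks for the permutation task.
#' @param warp_knots number of spline anchors (including the fixed endpoints).
#' @param warp_sigma anchor perturbation scale, fraction of window duration.
#' @param rng_seed seed used by [build_ssl_dataset()] for reproducibility.
#' @return A list of class `transform_config`.
#' @export
transform_config <- function(rotation_max_deg = 180, permute_segments = 4,
                             warp_knots = 4, warp_sigma = 0.2,
                             rng_seed = 1L) {
  stopifnot(permute_segments >= 2, warp_knots >= 2, warp_sigma > 0)
  structure(list(rotation_max_deg = rotation_max_deg,
                 permute_segments = as.integer(permute_segments),
                 warp_knots = as.integer(warp_knots),
                 warp_sigma = warp_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "transform_config")
}

#' Network architecture configuration
#'
#' Defaults are the published architecture: the raw-signal branch (ConvR) has
#' 64 kernels of size 32 then 128 kernels of size 8, with max-pooling of size
#' 16 and stride 4 after the first block and dropout rates 0.1/0.2; the
#' spectrogram branch (ConvS) has 64 5x5 kernels then 128 3x3 kernels, 2x2
#' max-pooling with stride 2 and dropout 0.1 after each block. Global average
#' pooling closes ConvR and global max pooling closes ConvS in pretext mode.
#' The shared-task heads have size 128, the branch LSTMs size 128 with
#' dropout 0.1, and the post-fusion dense layer size 256 before a single
#' linear output. Widths are exposed so scaled-down models can be built for
#' small synthetic problems without touching the published defaults.
#'
#' @param r_filters1,r_kernel1 ConvR block-1 kernel count and length.
#' @param r_pool_size,r_pool_stride ConvR max-pooling size and stride.
#' @param r_dropout1,r_dropout2 ConvR dropout rates after blocks 1 and 2.
#' @param r_filters2,r_kernel2 ConvR block-2 kernel count and length.
#' @param s_filters1,s_kernel1 ConvS block-1 kernel count and 2-vector size.
#' @param s_pool ConvS max-pooling size (= stride), 2-vector.
#' @param s_dropout1,s_dropout2 ConvS dropout rates.
#' @param s_filters2,s_kernel2 ConvS block-2 kernel count and 2-vector size.
#' @param task_head width of each shared pretext-task layer.
#' @param n_tasks number of pretext tasks (rotation, permutation, time warp).
#' @param lstm LSTM state size of each branch LSTM.
#' @param lstm_dropout dropout applied to LSTM input sequences.
#' @param fusion width of the post-fusion dense layer.
#' @param fusion_op how branch features are fused: `"concat"` or `"add"`.
#' @return A list of class `network_config`.
#' @export
network_config <- function(r_filters1 = 64L, r_kernel1 = 32L,
                           r_pool_size = 16L, r_pool_stride = 4L,
                           r_dropout1 = 0.1, r_filters2 = 128L,
                           r_kernel2 = 8L, r_dropout2 = 0.2,
                           s_filters1 = 64L, s_kernel1 = c(5L, 5L),
                           s_pool = c(2L, 2L), s_dropout1 = 0.1,
                           s_filters2 = 128L, s_kernel2 = c(3L, 3L),
                           s_dropout2 = 0.1,
                           task_head = 128L, n_tasks = 3L,
                           lstm = 128L, lstm_dropout = 0.1,
                           fusion = 256L, fusion_op = c("concat", "add")) {
  fusion_op <- match.arg(fusion_op)
  cfg <- list(r_filters1 = as.integer(r_filters1), r_kernel1 = as.integer(r_kernel1),
              r_pool_size = as.integer(r_pool_size), r_pool_stride = as.integer(r_pool_stride),
              r_dropout1 = r_dropout1, r_filters2 = as.integer(r_filters2),
              r_kernel2 = as.integer(r_kernel2), r_dropout2 = r_dropout2,
              s_filters1 = as.integer(s_filters1), s_kernel1 = as.integer(s_kernel1),
              s_pool = as.integer(s_pool), s_dropout1 = s_dropout1,
              s_filters2 = as.integer(s_filters2), s_kernel2 = as.integer(s_kernel2),
              s_dropout2 = s_dropout2,
              task_head = as.integer(task_head), n_tasks = as.integer(n_tasks),
              lstm = as.integer(lstm), lstm_dropout = lstm_dropout,
              fusion = as.integer(fusion), fusion_op = fusion_op)
  structure(cfg, class = "network_config")
}

#' Training configuration
#'
#' Defaults follow the published regime: 35 epochs, batch size 32, Adam with
#' learning rate 1e-4, a random 20% validation split (stratified by subject
#' to avoid window-level identity leakage), early stopping and
#' reduce-on-plateau learning-rate scheduling.
#'
#' @param epochs maximal number of epochs.
#' @param batch_size minibatch size.
#' @param learning_rate initial Adam learning rate.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (best-epoch weights are restored).
#' @param lr_factor,lr_patience,lr_min plateau schedule: multiply the rate by
#'   `lr_factor` after `lr_patience` stagnant epochs, never below `lr_min`.
#' @param val_fraction fraction of training samples held out for validation.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 35L, batch_size = 32L, learning_rate = 1e-4,
                         early_stop_patience = 10L, lr_factor = 0.5,
                         lr_patience = 5L, lr_min = 1e-6,
                         val_fraction = 0.2, seed = 1L) {
  stopifnot(epochs >= 1, val_fraction > 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 lr_min = lr_min, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Loss configuration
#'
#' `alphas` are the per-task weights of the multi-shared-task loss (a
#' weighted sum of per-task binary cross-entropies). `positive_weight`
#' compensates the 3:1 negative:positive imbalance each task head sees when
#' every window contributes one original and three singly-transformed
#' samples. `huber_delta` is the transition point of the Huber regression
#' loss used for fine-tuning.
#'
#' @param alphas numeric vector of per-task loss weights.
#' @param positive_weight weight of positive samples in each task's BCE.
#' @param huber_delta Huber loss delta.
#' @param prob_clip_eps probabilities are clipped to
#'   `[prob_clip_eps, 1 - prob_clip_eps]` before taking logs.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(alphas = c(1, 1, 1), positive_weight = 3,
                        huber_delta = 1, prob_clip_eps = 1e-7) {
  stopifnot(all(alphas >= 0), huber_delta > 0, prob_clip_eps > 0)
  structure(list(alphas = alphas, positive_weight = positive_weight,
                 huber_delta = huber_delta, prob_clip_eps = prob_clip_eps),
            class = "loss_config")
}

#' Synthetic cohort configuration
#'
#' Describes the simulated Parkinson's cohort. Protocol group A performs 4
#' rounds of scripted activities of daily living; group B one continuous
#' homelike session scored at its beginning and end. Severity-dependent
#' structure: 4-6 Hz tremor power grows with severity above an onset
#' threshold (stronger on the wrist), while voluntary movement amplitude in
#' the 0.5-3 Hz band shrinks with severity (bradykinesia).
#'
#' @param n_subjects number of subjects.
#' @param group_a_fraction fraction assigned to protocol group A.
#' @param round_duration_s duration of each group-A round, seconds.
#' @param session_duration_s duration of the group-B continuous session.
#' @param exam_s length of the UPDRS examination excluded at the start of
#'   each round (0 disables exclusion intervals).
#' @param activities group-A activity labels.
#' @param activities_b group-B station labels.
#' @param severity_off_range,severity_on_range integer UPDRS-III ranges in
#'   the OFF and ON medication states.
#' @param tremor_f_range tremor frequency band, Hz.
#' @param tremor_amp_coeff tremor amplitude coefficient, deg/s at severity 60
#'   above onset.
#' @param tremor_onset severity below which no tremor is generated.
#' @param movement_amp baseline voluntary-movement amplitude A0, deg/s.
#' @param brady_slope fractional amplitude loss per 60 severity points.
#' @param movement_band voluntary movement band, Hz.
#' @param noise_sigma additive Gaussian noise SD, deg/s.
#' @param wearoff_prob probability that a group-A subject reverts to OFF in
#'   the final round.
#' @param fs sampling rate, Hz (the pipeline asserts 64).
#' @param seed RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 24L, group_a_fraction = 15 / 24,
                          round_duration_s = 600, session_duration_s = 1800,
                          exam_s = 30,
                          activities = c("ambulation", "resting", "cutting food",
                                         "dressing", "drinking",
                                         "unpacking groceries", "hygiene"),
                          activities_b = c("laundry", "watching television",
                                           "snacking", "desk work"),
                          severity_off_range = c(12L, 60L),
                          severity_on_range = c(4L, 38L),
                          tremor_f_range = c(4, 6), tremor_amp_coeff = 25,
                          tremor_onset = 15, movement_amp = 30,
                          brady_slope = 0.6, movement_band = c(0.5, 3),
                          noise_sigma = 2, wearoff_prob = 0.25,
                          fs = 64, seed = 1L) {
  stopifnot(n_subjects >= 2, fs == 64,
            severity_off_range[1] < severity_off_range[2],
            severity_on_range[1] < severity_on_range[2],
            tremor_f_range[1] < tremor_f_range[2])
  structure(list(n_subjects = as.integer(n_subjects),
                 group_a_fraction = group_a_fraction,
                 round_duration_s = round_duration_s,
                 session_duration_s = session_duration_s,
                 exam_s = exam_s, activities = activities,
                 activities_b = activities_b,
                 severity_off_range = as.integer(severity_off_range),
                 severity_on_range = as.integer(severity_on_range),
                 tremor_f_range = tremor_f_range,
                 tremor_amp_coeff = tremor_amp_coeff,
                 tremor_onset = tremor_onset, movement_amp = movement_amp,
                 brady_slope = brady_slope, movement_band = movement_band,
                 noise_sigma = noise_sigma, wearoff_prob = wearoff_prob,
                 fs = fs, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Derive a per-stage seed from a master seed
#'
#' Stages are seeded as `master_seed + stage ordinal` (modulo 2^31 - 1) so
#' each stage is independently reproducible from the master seed alone.
#'
#' @param master_seed integer master seed.
#' @param stage stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(master_seed,
                       stage = c("simulate", "preprocess", "ssl", "pretrain",
                                 "finetune", "evaluate")) {
  stage <- match.arg(stage)
  ord <- match(stage, c("simulate", "preprocess", "ssl", "pretrain",
                        "finetune", "evaluate"))
  as.integer((as.numeric(master_seed) * 131L + ord * 7919L) %% (2^31 - 1))
}
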