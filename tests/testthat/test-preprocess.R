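test_that("band-pass FIR design hits -3 dB edges and suppresses the stopband", {
  k <- design_bandpass_fir(0.5, 15, 64, 513)
  expect_equal(fir_response(k, 0.5), -3, tolerance = 0.5 / 3)
  expect_equal(fir_response(k, 15), -3, tolerance = 0.5 / 3)
  expect_lt(abs(fir_response(k, 7)), 0.5)        # passband center ~ 0 dB
  expect_lt(fir_response(k, 30), -20)            # stopband
  expect_lt(fir_response(k, 0.05), -20)
  # linear phase: coefficients symmetric to machine precision
  expect_lt(max(abs(k$h - rev(k$h))), 1e-12)
  expect_error(design_bandpass_fir(15, 0.5, 64, 513), "band edges")
  expect_error(design_bandpass_fir(0.5, 15, 64, 512), "odd")
})

test_that("zero-phase filtering preserves passband and kills drift", {
  k <- design_bandpass_fir(0.5, 15, 64, 513)
  n <- 6400
  t <- (0:(n - 1)) / 64
  mid <- 2000:4400  # away from edge transients

  z <- toy_recording(100, signal = matrix(0, n, 6))
  expect_true(all(apply_filter(z, k)$data == 0))

  s5 <- toy_recording(100, signal = matrix(sin(2 * pi * 5 * t), n, 6))
  f5 <- apply_filter(s5, k)
  expect_equal(max(abs(f5$data[mid, 1])), 1, tolerance = 0.1)
  expect_equal(nrow(f5$data), n)
  # zero phase: filtered 5 Hz sine stays aligned with the input
  expect_gt(stats::cor(f5$data[mid, 1], s5$data[mid, 1]), 0.999)

  drift <- toy_recording(100, signal = matrix(sin(2 * pi * 0.05 * t), n, 6))
  fd <- apply_filter(drift, k)
  expect_lt(max(abs(fd$data[mid, 1])), 0.1)  # >= 90% attenuation

  short <- toy_recording(5, signal = matrix(1, 320, 6))
  expect_error(apply_filter(short, k), "longer than the signal")
})

test_that("windowing cuts kept intervals independently and drops partials", {
  # 60 s, no annotation -> 12 windows of 320 samples
  seg <- segment_windows(toy_recording(60))
  expect_equal(dim(seg$x), c(12, 320, 6))
  # 13 s -> floor(13/5) = 2 windows
  expect_equal(dim(segment_windows(toy_recording(13))$x)[1], 2)
  # 30 s with exclusion [10, 20) -> 2 + 2 windows
  seg3 <- segment_windows(toy_recording(30, exclusions = list(c(10, 20))))
  expect_equal(dim(seg3$x)[1], 4)
  expect_equal(seg3$meta$start_s, c(0, 5, 20, 25))
  # windows never overlap an exclusion
  expect_false(any(seg3$meta$start_s < 20 & seg3$meta$start_s + 5 > 10 &
                     seg3$meta$start_s >= 10))
})

test_that("windows carry round, score and dominant activity labels", {
  rounds <- list(
    list(index = 1L, start_s = 0, end_s = 15, updrs = 27L, med_state = "OFF",
         activities = list(list(label = "resting", start_s = 0, end_s = 8),
                           list(label = "ambulation", start_s = 8, end_s = 15))),
    list(index = 2L, start_s = 15, end_s = 30, updrs = 14L, med_state = "ON",
         activities = list(list(label = "drinking", start_s = 15, end_s = 30))))
  seg <- segment_windows(toy_recording(30, rounds = rounds))
  expect_equal(dim(seg$x)[1], 6)
  expect_equal(seg$meta$round, c(1, 1, 1, 2, 2, 2))
  expect_equal(seg$meta$updrs, c(27, 27, 27, 14, 14, 14))
  # dominant label: window [5,10) overlaps resting 3 s, ambulation 2 s
  expect_equal(seg$meta$activity,
               c("resting", "resting", "ambulation",
                 "drinking", "drinking", "drinking"))
  # windows restart at each round boundary: conservation across rounds
  expect_equal(sum(seg$meta$round == 1), floor(15 / 5))
})

test_that("window counts follow the per-interval floor rule", {
  # property: sum of windows = sum over kept intervals of floor(len/5)
  set.seed(4)
  for (i in 1:20) {
    dur <- sample(20:80, 1)
    ex0 <- sort(stats::runif(2, 1, dur - 1))
    rec <- toy_recording(dur, exclusions = list(ex0))
    kept <- c(ex0[1] - 0, dur - ex0[2])
    expect_equal(dim(segment_windows(rec)$x)[1], sum(floor(kept / 5)))
  }
})

test_that("spectrogram shape, floor and tone localization", {
  w <- rand_window(seed = 1)
  s <- compute_spectrogram(w)
  expect_equal(dim(s), c(33, 43, 6))  # (64/2+1) x (floor((320-64)/6)+1) x 6
  # shape is a pure function of the config, identical for any input
  expect_equal(dim(compute_spectrogram(rand_window(seed = 2))), dim(s))

  s0 <- compute_spectrogram(matrix(0, 320, 6))
  expect_true(all(s0 == -80))

  tone <- matrix(0, 320, 6)
  tone[, 1] <- sin(2 * pi * 5 * (0:319) / 64)
  st <- compute_spectrogram(tone)
  expect_true(all(apply(st[, , 1], 2, which.max) == 6))  # 5 Hz -> bin 6

  expect_error(compute_spectrogram(matrix(0, 32, 6)), "longer than")
})

test_that("scaling a window shifts non-floored dB values by exactly 20*log10(c)", {
  w <- rand_window(seed = 3)
  s1 <- compute_spectrogram(w)
  s2 <- compute_spectrogram(3 * w)
  live <- s1 > -80 & s2 > -80
  expect_lt(max(abs((s2 - s1)[live] - 20 * log10(3))), 1e-9)
})

test_that("band crop keeps only bins at or below the limit", {
  s <- compute_spectrogram(rand_window(seed = 4), stft_config(crop_hz = 16))
  expect_equal(dim(s), c(17, 43, 6))
  expect_true(all(attr(s, "freq_axis") <= 16))
})

test_that("normalization statistics come from the fitted split only", {
  ws <- small_cohort_ws(n_subjects = 3, round_s = 30, exam_s = 0)
  idx <- ws$meta$subject %in% unique(ws$meta$subject)[1:2]
  norm <- fit_normalizer(subset_window_set(ws, idx))
  expect_equal(norm$fitted_on, sort(unique(ws$meta$subject))[1:2])
  wsn <- apply_normalizer(ws, norm)
  tr <- subset_window_set(wsn, idx)
  # per-channel z-scoring is exact on the fitted windows
  for (ch in 1:6) {
    expect_equal(mean(tr$x_r[, , ch]), 0, tolerance = 1e-8)
    expect_equal(stats::sd(as.numeric(tr$x_r[, , ch])), 1, tolerance = 1e-6)
  }
  expect_equal(range(tr$x_s), c(0, 1), tolerance = 1e-12)
})
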