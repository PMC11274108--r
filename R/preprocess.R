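#' Design the band-pass FIR filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR band-pass whose magnitude
#' response is -3 dB at `low_hz` and `high_hz`. The window method places the
#' -6 dB point at the nominal design edge, so the design band is widened
#' numerically (one-dimensional root finding per edge on the evaluated
#' frequency response) until the realized response crosses -3 dB at the
#' requested frequencies. The default 513 taps at 64 Hz give a transition
#' band of roughly 0.4 Hz and > 50 dB stopband attenuation.
#'
#' @param low_hz,high_hz -3 dB band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param num_taps odd number of filter coefficients.
#' @return A list of class `fir_kernel` with elements `h` (coefficients),
#'   `low_hz`, `high_hz`, `fs`, `num_taps`.
#' @export
design_bandpass_fir <- function(low_hz = 0.5, high_hz = 15, fs = 64,
                                num_taps = 513L) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("invalid band edges: need 0 < low_hz < high_hz < fs/2")
  if (num_taps %% 2 != 1) stop("num_taps must be odd")

  design <- function(lo, hi)
    signal::fir1(num_taps - 1L, c(lo, hi) / (fs / 2), type = "pass")
  resp_db <- function(h, f) {
    H <- sum(h * exp(-2i * pi * f / fs * (seq_along(h) - 1)))
    20 * log10(Mod(H))
  }

  # Widen each design edge until the realized response is -3 dB at the
  # requested frequency; two passes absorb the (tiny) edge interaction.
  lo <- low_hz
  hi <- high_hz
  tw <- 4 * fs / num_taps  # generous transition-width bound for the bracket
  for (pass in 1:2) {
    lo <- stats::uniroot(function(e) resp_db(design(e, hi), low_hz) + 3,
                         lower = max(low_hz - tw, 1e-3 * fs),
                         upper = low_hz, tol = 1e-6)$root
    hi <- stats::uniroot(function(e) resp_db(design(lo, e), high_hz) + 3,
                         lower = high_hz,
                         upper = min(high_hz + tw, fs / 2 - 1e-3 * fs),
                         tol = 1e-6)$root
  }
  structure(list(h = design(lo, hi), low_hz = low_hz, high_hz = high_hz,
                 fs = fs, num_taps = as.integer(num_taps)),
            class = "fir_kernel")
}

#' Evaluate a FIR kernel's magnitude response
#'
#' @param kernel a `fir_kernel` from [design_bandpass_fir()].
#' @param f frequencies in Hz.
#' @param db return decibels (default) or linear magnitude.
#' @return Numeric vector of |H(f)|, in dB by default.
#' @export
fir_response <- function(kernel, f, db = TRUE) {
  h <- kernel$h
  n <- seq_along(h) - 1
  mag <- vapply(f, function(fi)
    Mod(sum(h * exp(-2i * pi * fi / kernel$fs * n))), numeric(1))
  if (db) 20 * log10(mag) else mag
}

#' Zero-phase band-pass filtering of a recording
#'
#' Applies the FIR kernel forward and backward (equivalently, convolution
#' with the kernel's autocorrelation), so the output has exactly zero phase
#' and no group delay; signal length is preserved, edges are zero-padded.
#'
#' @param recording a `sensor_recording` (see [read_recording()]).
#' @param kernel a `fir_kernel`.
#' @return The recording with every channel filtered.
#' @export
apply_filter <- function(recording, kernel) {
  x <- recording$data
  n <- length(kernel$h)
  if (n > nrow(x)) stop("filter kernel longer than the signal")
  g <- stats::convolve(kernel$h, rev(kernel$h), type = "open")  # h * h
  for (j in seq_len(ncol(x))) {
    full <- stats::convolve(x[, j], rev(g), type = "open")
    x[, j] <- full[n:(n + nrow(x) - 1L)]
  }
  recording$data <- x
  recording
}

# Subtract exclusion intervals from [s, e); returns a list of kept intervals.
subtract_intervals <- function(s, e, exclusions) {
  kept <- list(c(s, e))
  for (ex in exclusions) {
    nxt <- list()
    for (iv in kept) {
      if (ex[2] <= iv[1] || ex[1] >= iv[2]) { nxt[[length(nxt) + 1L]] <- iv; next }
      if (ex[1] > iv[1]) nxt[[length(nxt) + 1L]] <- c(iv[1], ex[1])
      if (ex[2] < iv[2]) nxt[[length(nxt) + 1L]] <- c(ex[2], iv[2])
    }
    kept <- nxt
  }
  kept
}

dominant_activity <- function(activities, w0, w1) {
  if (length(activities) == 0) return(NA_character_)
  ov <- vapply(activities, function(a)
    max(0, min(a$end_s, w1) - max(a$start_s, w0)), numeric(1))
  if (max(ov) <= 0) return(NA_character_)
  activities[[which.max(ov)]]$label
}

#' Segment a recording into non-overlapping 5 s windows
#'
#' Each round interval (or the whole recording when no rounds are annotated)
#' has its exclusion intervals removed; every remaining contiguous stretch is
#' cut independently into `floor(length / window_s)` windows starting at the
#' stretch's beginning, so windows never straddle an exclusion or a round
#' boundary. Trailing partial windows are discarded. Each window carries its
#' round index, medication state, clinical score and dominant activity label.
#'
#' @param recording a (filtered) `sensor_recording`.
#' @param window_s window duration in seconds.
#' @return A list with `x` (array `N x window_samples x 6`) and `meta`
#'   (data.frame with subject, round, med_state, updrs, activity, start_s).
#' @export
segment_windows <- function(recording, window_s = 5) {
  fs <- recording$fs
  L <- as.integer(round(window_s * fs))
  rounds <- recording$rounds
  if (length(rounds) == 0)
    rounds <- list(list(index = NA_integer_, start_s = 0,
                        end_s = recording$duration_s, updrs = NA_integer_,
                        med_state = NA_character_, activities = list()))
  xs <- list(); meta <- list()
  for (rd in rounds) {
    kept <- subtract_intervals(rd$start_s, rd$end_s, recording$exclusions)
    for (iv in kept) {
      nwin <- floor((iv[2] - iv[1]) / window_s)
      if (nwin < 1) next
      for (w in seq_len(nwin)) {
        t0 <- iv[1] + (w - 1) * window_s
        i0 <- as.integer(round(t0 * fs)) + 1L
        xs[[length(xs) + 1L]] <- recording$data[i0:(i0 + L - 1L), , drop = FALSE]
        meta[[length(meta) + 1L]] <- data.frame(
          subject = recording$subject_id, round = rd$index,
          med_state = if (is.null(rd$med_state)) NA_character_ else rd$med_state,
          updrs = if (is.null(rd$updrs)) NA_integer_ else rd$updrs,
          activity = dominant_activity(rd$activities, t0, t0 + window_s),
          start_s = t0, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(xs) == 0)
    return(list(x = array(0, c(0, L, ncol(recording$data))),
                meta = data.frame()))
  x <- array(0, c(length(xs), L, ncol(recording$data)))
  for (i in seq_along(xs)) x[i, , ] <- xs[[i]]
  list(x = x, meta = do.call(rbind, meta))
}

#' Compute the per-channel spectrogram of one window
#'
#' One-sided magnitude STFT with a Kaiser window, reported in dB and floored
#' at `log_floor_db`. The dB value is `20*log10(max(|STFT|, floor))` so that
#' scaling a window by `c` shifts every non-floored value by exactly
#' `20*log10(c)`. With the defaults (1 s window, hop 6, 64 Hz) a 320-sample
#' window maps to a 33 x 43 x channels array.
#'
#' @param window numeric matrix, samples x channels.
#' @param config an [stft_config()].
#' @param fs sampling rate in Hz.
#' @return Array `freq_bins x frames x channels` with attributes `freq_axis`
#'   (Hz) and `time_axis` (s, frame centers).
#' @export
compute_spectrogram <- function(window, config = stft_config(), fs = 64) {
  W <- as.integer(round(config$win_s * fs))
  L <- nrow(window)
  if (W > L) stop("STFT window longer than the signal window")
  hop <- W - as.integer(round(config$overlap_frac * W))
  nfft <- if (is.null(config$nfft)) W else as.integer(config$nfft)
  stopifnot(nfft >= W)
  nb <- nfft %/% 2L + 1L
  starts <- seq(1L, L - W + 1L, by = hop)
  kw <- signal::kaiser(W, config$kaiser_beta)
  floor_mag <- 10^(config$log_floor_db / 20)
  freq <- (0:(nb - 1L)) * fs / nfft
  keep <- if (is.null(config$crop_hz)) seq_len(nb)
          else which(freq <= config$crop_hz + 1e-9)
  idx <- outer(0:(W - 1L), starts, "+")
  out <- array(0, c(length(keep), length(starts), ncol(window)))
  for (ch in seq_len(ncol(window))) {
    fr <- matrix(window[, ch][idx], nrow = W) * kw
    if (nfft > W) fr <- rbind(fr, matrix(0, nfft - W, ncol(fr)))
    Z <- stats::mvfft(fr)
    out[, , ch] <- 20 * log10(pmax(Mod(Z[keep, , drop = FALSE]), floor_mag))
  }
  attr(out, "freq_axis") <- freq[keep]
  attr(out, "time_axis") <- (starts - 1L + W / 2) / fs
  out
}

# Spectrograms for an N x L x C array of windows -> N x bins x frames x C.
spectrogram_batch <- function(x, config = stft_config(), fs = 64) {
  n <- dim(x)[1]
  s1 <- compute_spectrogram(matrix(0, dim(x)[2], dim(x)[3]), config, fs)
  out <- array(0, c(n, dim(s1)))
  for (i in seq_len(n)) out[i, , , ] <- compute_spectrogram(x[i, , ], config, fs)
  out
}

#' Preprocess one recording into windows and spectrograms
#'
#' Runs the standard chain: zero-phase band-pass filtering, exclusion-aware
#' 5 s windowing, and per-window spectrograms.
#'
#' @param recording a `sensor_recording`.
#' @param kernel a `fir_kernel`; `NULL` designs the default 0.5-15 Hz filter.
#' @param window_s window duration in seconds.
#' @param stft an [stft_config()].
#' @return A `window_set`: list with `x_r` (N x 320 x 6), `x_s`
#'   (N x 33 x 43 x 6) and `meta`.
#' @export
preprocess_recording <- function(recording, kernel = NULL, window_s = 5,
                                 stft = stft_config()) {
  if (recording$fs != 64) stop("pipeline assumes fs = 64 Hz")
  if (is.null(kernel)) kernel <- design_bandpass_fir(fs = recording$fs)
  filtered <- apply_filter(recording, kernel)
  seg <- segment_windows(filtered, window_s)
  x_s <- spectrogram_batch(seg$x, stft, recording$fs)
  structure(list(x_r = seg$x, x_s = x_s, meta = seg$meta),
            class = "window_set")
}

#' Preprocess a list of recordings into one combined window set
#'
#' @param recordings list of `sensor_recording` objects.
#' @param ... passed to [preprocess_recording()].
#' @return A combined `window_set`.
#' @export
preprocess_cohort <- function(recordings, ...) {
  kernel <- design_bandpass_fir()
  sets <- lapply(recordings, preprocess_recording, kernel = kernel, ...)
  bind_window_sets(sets)
}

#' Combine window sets row-wise
#' @param sets list of `window_set` objects.
#' @return One `window_set`.
#' @export
bind_window_sets <- function(sets) {
  sets <- Filter(function(s) nrow(s$meta) > 0, sets)
  stopifnot(length(sets) > 0)
  n <- sum(vapply(sets, function(s) dim(s$x_r)[1], integer(1)))
  dr <- dim(sets[[1]]$x_r)[-1]; ds <- dim(sets[[1]]$x_s)[-1]
  x_r <- array(0, c(n, dr)); x_s <- array(0, c(n, ds))
  at <- 0L
  for (s in sets) {
    k <- dim(s$x_r)[1]
    x_r[at + seq_len(k), , ] <- s$x_r
    x_s[at + seq_len(k), , , ] <- s$x_s
    at <- at + k
  }
  structure(list(x_r = x_r, x_s = x_s,
                 meta = do.call(rbind, lapply(sets, `[[`, "meta"))),
            class = "window_set")
}

#' Subset a window set by row index
#' @param ws a `window_set`.
#' @param idx integer or logical index over windows.
#' @return The subsetted `window_set`.
#' @export
subset_window_set <- function(ws, idx) {
  structure(list(x_r = ws$x_r[idx, , , drop = FALSE],
                 x_s = ws$x_s[idx, , , , drop = FALSE],
                 meta = ws$meta[idx, , drop = FALSE]),
            class = "window_set")
}

#' Fit input-normalization statistics on a training split
#'
#' Raw windows are z-scored per channel; spectrograms are min-max scaled to
#' `[0, 1]`. Statistics are computed on the supplied (training) windows only
#' and stored together with the subjects that contributed them, so leakage
#' audits can verify that no test subject influenced normalization.
#'
#' @param ws a `window_set` containing only training windows.
#' @return A list of class `normalizer`.
#' @export
fit_normalizer <- function(ws) {
  nch <- dim(ws$x_r)[3]
  mu <- sd <- numeric(nch)
  for (ch in seq_len(nch)) {
    v <- ws$x_r[, , ch]
    mu[ch] <- mean(v)
    sd[ch] <- stats::sd(as.numeric(v))
    if (sd[ch] < 1e-12) sd[ch] <- 1
  }
  structure(list(mu = mu, sd = sd,
                 s_min = min(ws$x_s), s_max = max(ws$x_s),
                 fitted_on = sort(unique(ws$meta$subject))),
            class = "normalizer")
}

#' Apply fitted normalization to a window set
#' @param ws a `window_set`.
#' @param norm a `normalizer` from [fit_normalizer()].
#' @return The normalized `window_set`.
#' @export
apply_normalizer <- function(ws, norm) {
  for (ch in seq_along(norm$mu))
    ws$x_r[, , ch] <- (ws$x_r[, , ch] - norm$mu[ch]) / norm$sd[ch]
  rng <- max(norm$s_max - norm$s_min, 1e-12)
  ws$x_s <- (ws$x_s - norm$s_min) / rng
  ws
}
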