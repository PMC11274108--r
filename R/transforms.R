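# Random 3-D rotation matrix: axis uniform on the sphere, angle uniform in
# +/- max_deg (Rodrigues' formula).
random_rotation_matrix <- function(max_deg) {
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  theta <- stats::runif(1, -max_deg, max_deg) * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotation pretext transformation
#'
#' Interprets the 6 channels as two 3-axis vectors per timestep (wrist then
#' ankle) and rotates each sensor site by an independent random 3-D rotation,
#' emulating a different sensor placement. Per-timestep Euclidean norms of
#' each triplet are preserved exactly (orthogonality).
#'
#' @param window numeric matrix, samples x channels (channels a multiple of 3).
#' @param max_deg maximal rotation angle in degrees.
#' @return The rotated window.
#' @export
rotate_window <- function(window, max_deg = 180) {
  if (ncol(window) %% 3 != 0)
    stop("channel count must be a multiple of 3 to rotate sensor triplets")
  for (s in seq_len(ncol(window) %/% 3)) {
    cols <- (s - 1) * 3 + 1:3
    R <- random_rotation_matrix(max_deg)
    window[, cols] <- window[, cols, drop = FALSE] %*% t(R)
  }
  window
}

#' Permutation pretext transformation
#'
#' Splits the window into `n_segments` contiguous blocks (the last block
#' absorbs any remainder) and reorders them by a random non-identity
#' permutation, disrupting the temporal sequence while preserving the value
#' multiset exactly.
#'
#' @param window numeric matrix, samples x channels.
#' @param n_segments number of blocks (>= 2).
#' @return The permuted window.
#' @export
permute_window <- function(window, n_segments = 4) {
  L <- nrow(window)
  if (n_segments > L) stop("more segments than samples")
  stopifnot(n_segments >= 2)
  base <- L %/% n_segments
  starts <- (seq_len(n_segments) - 1) * base + 1
  ends <- c(starts[-1] - 1, L)
  perm <- sample.int(n_segments)
  while (all(perm == seq_len(n_segments))) perm <- sample.int(n_segments)
  idx <- unlist(lapply(perm, function(p) starts[p]:ends[p]))
  window[idx, , drop = FALSE]
}

#' Time-warp pretext transformation
#'
#' Builds a smooth monotone warping function from a monotone cubic spline
#' through `warp_knots` equally spaced anchors whose interior positions are
#' perturbed by Gaussian noise of SD `warp_sigma` (as a fraction of the
#' window duration; endpoints stay fixed), then resamples every channel by
#' linear interpolation along the warp. Output length equals input length
#' and endpoint samples are unchanged. Non-monotone perturbations are
#' resampled.
#'
#' @param window numeric matrix, samples x channels.
#' @param warp_knots number of spline anchors (>= 2, including endpoints).
#' @param warp_sigma perturbation scale.
#' @return The warped window.
#' @export
time_warp_window <- function(window, warp_knots = 4, warp_sigma = 0.2) {
  stopifnot(warp_knots >= 2, warp_sigma > 0)
  L <- nrow(window)
  anchors <- seq(0, 1, length.out = warp_knots)
  for (try in 1:200) {
    y <- anchors
    if (warp_knots > 2) {
      mid <- 2:(warp_knots - 1)
      y[mid] <- anchors[mid] + stats::rnorm(length(mid), 0, warp_sigma)
    }
    if (all(diff(y) > 1e-6) && all(y >= 0) && all(y <= 1)) break
    if (try == 200) stop("could not draw a monotone warp; reduce warp_sigma")
  }
  warp <- stats::splinefun(anchors, y, method = "hyman")
  s <- seq(0, 1, length.out = L)
  src <- pmin(pmax(warp(s), 0), 1) * (L - 1) + 1
  out <- window
  for (ch in seq_len(ncol(window)))
    out[, ch] <- stats::approx(seq_len(L), window[, ch], xout = src,
                               rule = 2)$y
  out[1, ] <- window[1, ]
  out[L, ] <- window[L, ]
  out
}

#' Build a self-supervised pretext dataset from preprocessed windows
#'
#' For every input window, emits four samples: the untouched original with
#' pseudo-label `(0,0,0)` and one singly-transformed copy per pretext task
#' (rotation, permutation, time warp) with a one-hot pseudo-label.
#' Spectrograms are recomputed from each transformed raw signal, never
#' copied, and the output order is shuffled. Bit-identical under a fixed
#' `config$rng_seed`.
#'
#' @param ws a `window_set` of training windows.
#' @param config a [transform_config()].
#' @param stft an [stft_config()] used to recompute spectrograms.
#' @param fs sampling rate in Hz.
#' @return A list of class `ssl_dataset` with `x_r` (4N x L x C), `x_s`
#'   (4N x bins x frames x C), `y_p` (4N x 3), `t` (transform id 0..3) and
#'   `subject` (carried through for stratified splits).
#' @export
build_ssl_dataset <- function(ws, config = transform_config(),
                              stft = stft_config(), fs = 64) {
  n <- dim(ws$x_r)[1]
  L <- dim(ws$x_r)[2]; C <- dim(ws$x_r)[3]
  if (n == 0)
    return(structure(list(x_r = ws$x_r, x_s = ws$x_s,
                          y_p = matrix(0, 0, 3), t = integer(0),
                          subject = character(0)), class = "ssl_dataset"))
  set.seed(config$rng_seed)
  m <- 4L * n
  sdim <- dim(ws$x_s)[-1]
  x_r <- array(0, c(m, L, C)); x_s <- array(0, c(m, sdim))
  y_p <- matrix(0L, m, 3); tid <- integer(m); subj <- character(m)
  at <- 0L
  for (i in seq_len(n)) {
    w0 <- ws$x_r[i, , ]
    variants <- list(w0,
                     rotate_window(w0, config$rotation_max_deg),
                     permute_window(w0, config$permute_segments),
                     time_warp_window(w0, config$warp_knots, config$warp_sigma))
    for (t in 0:3) {
      at <- at + 1L
      x_r[at, , ] <- variants[[t + 1L]]
      x_s[at, , , ] <- if (t == 0) ws$x_s[i, , , ]
                       else compute_spectrogram(variants[[t + 1L]], stft, fs)
      if (t > 0) y_p[at, t] <- 1L
      tid[at] <- t
      subj[at] <- ws$meta$subject[i]
    }
  }
  ord <- sample.int(m)
  structure(list(x_r = x_r[ord, , , drop = FALSE],
                 x_s = x_s[ord, , , , drop = FALSE],
                 y_p = y_p[ord, , drop = FALSE], t = tid[ord],
                 subject = subj[ord]),
            class = "ssl_dataset")
}
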