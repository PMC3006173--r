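#' Remove the per-trial, per-channel mean
#'
#' DC offsets can survive acquisition high-pass filtering; the overall trial
#' mean is therefore subtracted from every channel of every trial before any
#' sub-band filtering.
#'
#' @param x A `trial_set`.
#' @return A `trial_set` whose per-trial per-channel means are zero.
#' @export
remove_trial_mean <- function(x) {
  stopifnot(inherits(x, "trial_set"))
  d <- dim(x$data)
  m <- rowMeans(matrix(x$data, d[1L] * d[2L], d[3L]))
  x$data <- x$data - array(m, dim = d)
  x
}

#' Per-band preprocessed tensor at 100 Hz
#'
#' Runs the fixed preprocessing chain on every usable channel of every
#' trial: per-trial mean removal, an anti-alias 220 Hz low-pass plus
#' decimation to 500 Hz (skipped when the input is already at 500 Hz),
#' zero-phase band-pass filtering into `band`, the Hilbert envelope when the
#' band asks for it, a 30 Hz anti-alias low-pass, and decimation to 100 Hz.
#' The output sample count is `ceiling(n_samples * 100 / fs)`.
#'
#' Channels masked unusable are dropped; the retained original channel
#' indices are recorded in the result. Trial labels travel with the tensor.
#'
#' @param x A `trial_set` sampled at 500 Hz or an integer multiple of it.
#' @param band A [subband_spec()].
#' @return An object of class `subband_tensor`: list with `data`
#'   `[n_trials, n_kept_channels, n_samples_100Hz]`, `fs_out = 100`, `band`,
#'   `t0_ms`, `labels`, `K`, `channels` (original indices), `session_id` and
#'   `edge_samples` (count of edge-contaminated samples at each end).
#' @export
preprocess_subband <- function(x, band) {
  stopifnot(inherits(x, "trial_set"), inherits(band, "subband_spec"))
  fs <- x$fs
  if (fs < 500 || fs %% 500 != 0) {
    stop("configuration error: fs must be 500 Hz or a multiple of it",
         call. = FALSE)
  }
  x <- remove_trial_mean(x)
  keep <- which(x$channel_mask)
  if (length(keep) == 0L) stop("no usable channels", call. = FALSE)
  d <- dim(x$data)
  decim1 <- fs / 500

  h_bp <- design_bandpass(band, 500)
  n_bp <- attr(h_bp, "order")
  h_lp30 <- design_lowpass(500, 30, df = 20)
  n_lp30 <- attr(h_lp30, "order")
  edge500 <- n_bp / 2 + n_lp30 / 2
  if (decim1 > 1) {
    h_lp220 <- design_lowpass(fs, 220, df = 60)
    edge500 <- edge500 + attr(h_lp220, "order") / (2 * decim1)
  }

  n_out <- ceiling(d[3L] * 100 / fs)
  out <- array(0, dim = c(d[1L], length(keep), n_out))
  for (tr in seq_len(d[1L])) {
    seg <- t(x$data[tr, keep, , drop = TRUE])
    if (length(keep) == 1L) seg <- matrix(x$data[tr, keep, ], ncol = 1L)
    if (decim1 > 1) {
      seg <- fft_filter_mat(seg, h_lp220)
      seg <- seg[seq(1L, nrow(seg), by = decim1), , drop = FALSE]
    }
    seg <- fft_filter_mat(seg, h_bp)
    if (band$use_envelope) seg <- apply_analytic(seg)
    seg <- fft_filter_mat(seg, h_lp30)
    seg <- seg[seq(1L, nrow(seg), by = 5L), , drop = FALSE]
    out[tr, , ] <- t(seg)
  }
  structure(
    list(data = out, fs_out = 100, band = band, t0_ms = x$t0_ms,
         labels = x$labels, K = x$K, channels = keep,
         session_id = x$session_id,
         edge_samples = as.integer(ceiling(edge500 / 5))),
    class = "subband_tensor"
  )
}

#' @export
print.subband_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat("<subband_tensor> band ", x$band$name, " (",
      if (x$band$use_envelope) "envelope" else "amplitude", "): ",
      d[1L], " trials x ", d[2L], " channels x ", d[3L], " samples @ ",
      x$fs_out, " Hz\n", sep = "")
  invisible(x)
}

#' Preprocess a trial set into several sub-bands
#'
#' @param x A `trial_set`.
#' @param bands Named list of [subband_spec()]s, default [default_bands()].
#' @return Named list of `subband_tensor`s.
#' @export
preprocess_bands <- function(x, bands = default_bands()) {
  lapply(bands, function(b) preprocess_subband(x, b))
}

#' Time axis of a subband tensor, ms relative to the alignment event
#'
#' @param x A `subband_tensor`.
#' @return Numeric vector, one entry per output sample.
#' @export
tensor_times <- function(x) {
  x$t0_ms + (seq_len(dim(x$data)[3L]) - 1) * 1000 / x$fs_out
}

#' Convert an ms window to sample indices of a subband tensor
#'
#' @param x A `subband_tensor`.
#' @param window_ms Length-2 numeric `(start, end)` in ms relative to the
#'   alignment event; samples with `start <= t < end` are selected.
#' @return Integer sample indices.
#' @export
window_samples <- function(x, window_ms) {
  t <- tensor_times(x)
  idx <- which(t >= window_ms[1L] & t < window_ms[2L])
  if (length(idx) < 2L) {
    stop("window [", window_ms[1L], ", ", window_ms[2L],
         ") ms lies outside the epoch", call. = FALSE)
  }
  idx
}

#' Baseline-normalized time-frequency map
#'
#' Short-time Fourier analysis (256 ms Hann windows, 75% overlap) of one
#' channel, power averaged over trials, each frequency bin expressed as
#' percent change relative to its mean power inside the baseline window:
#' `100 * (P(f,t) - Pbase(f)) / Pbase(f)`.
#'
#' @param x A `trial_set`.
#' @param baseline_window_ms Length-2 ms interval (relative to alignment)
#'   whose frames define the per-frequency baseline.
#' @param channel Channel index.
#' @param window_ms STFT window length in ms.
#' @param overlap Fractional window overlap.
#' @return Matrix `[freq, time]` of percent power change with attributes
#'   `freq_hz` and `time_ms` (frame centers).
#' @export
time_frequency_map <- function(x, baseline_window_ms, channel,
                               window_ms = 256, overlap = 0.75) {
  stopifnot(inherits(x, "trial_set"))
  d <- dim(x$data)
  nwin <- round(window_ms / 1000 * x$fs)
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, d[3L] - nwin + 1L, by = hop)
  centers_ms <- x$t0_ms + (starts - 1 + (nwin - 1) / 2) * 1000 / x$fs
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))  # Hann
  nf <- floor(nwin / 2) + 1L
  P <- matrix(0, nf, length(starts))
  for (tr in seq_len(d[1L])) {
    sig <- x$data[tr, channel, ]
    frames <- vapply(starts, function(s) sig[s:(s + nwin - 1L)] * win,
                     numeric(nwin))
    P <- P + Mod(mvfft(frames))[seq_len(nf), , drop = FALSE]^2
  }
  P <- P / d[1L]
  base_cols <- which(centers_ms >= baseline_window_ms[1L] &
                       centers_ms <= baseline_window_ms[2L])
  if (length(base_cols) == 0L) {
    stop("baseline window contains no analysis frames", call. = FALSE)
  }
  Pb <- rowMeans(P[, base_cols, drop = FALSE])
  if (any(Pb == 0)) stop("zero baseline power in at least one frequency bin",
                         call. = FALSE)
  out <- 100 * (P - Pb) / Pb
  attr(out, "freq_hz") <- (seq_len(nf) - 1) * x$fs / nwin
  attr(out, "time_ms") <- centers_ms
  out
}
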