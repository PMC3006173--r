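#' Sub-band definition
#'
#' Describes one analysis sub-band: passband edges, whether the band's
#' Hilbert envelope (rather than its signed amplitude) is carried forward,
#' and optionally a fixed FIR order. The canonical decomposition uses five
#' bands — 0.3–4, 4–10, 14–22, 22–30 and 48–200 Hz — with the envelope taken
#' for every band above the delta band.
#'
#' @param low,high Passband edges, Hz; `0 < low < high`.
#' @param use_envelope Carry the Hilbert envelope instead of the signed
#'   band-passed amplitude.
#' @param filter_order Optional even FIR order; when `NULL` the order is
#'   derived from the transition-width rule (see [design_bandpass()]).
#' @param name Band label.
#' @return An object of class `subband_spec`.
#' @export
subband_spec <- function(low, high, use_envelope = TRUE,
                         filter_order = NULL,
                         name = paste0(low, "-", high, "Hz")) {
  if (!(low > 0 && high > low)) {
    stop("configuration error: need 0 < low < high", call. = FALSE)
  }
  if (!is.null(filter_order) &&
      (filter_order < 2 || filter_order %% 2 != 0)) {
    stop("configuration error: filter_order must be even and >= 2",
         call. = FALSE)
  }
  structure(list(low = low, high = high, use_envelope = isTRUE(use_envelope),
                 filter_order = filter_order, name = name),
            class = "subband_spec")
}

#' The five canonical sub-bands
#'
#' @param which Optional character vector of band names to keep, e.g.
#'   `c("delta", "gamma")`.
#' @return Named list of [subband_spec()] objects: `delta` (0.3–4 Hz, signed
#'   amplitude), `theta` (4–10), `beta1` (14–22), `beta2` (22–30) and `gamma`
#'   (48–200), the last four as envelopes.
#' @export
default_bands <- function(which = NULL) {
  bands <- list(
    delta = subband_spec(0.3, 4,  use_envelope = FALSE, name = "delta"),
    theta = subband_spec(4, 10,   name = "theta"),
    beta1 = subband_spec(14, 22,  name = "beta1"),
    beta2 = subband_spec(22, 30,  name = "beta2"),
    gamma = subband_spec(48, 200, name = "gamma")
  )
  if (!is.null(which)) bands <- bands[which]
  bands
}

# transition width rule: at least 4 Hz, proportionally wider for bands with
# a high low edge; Blackman main-lobe factor 5.5 sets the order
band_transition <- function(low) max(0.25 * low, 4)

#' Design a linear-phase band-pass FIR filter
#'
#' Windowed-sinc design with a Blackman window. The magnitude response is
#' 0.5 (−6 dB) at each band edge — a property of the symmetric window design
#' at any order — and unity mid-band. The order is the smallest even integer
#' `N >= 5.5 * fs / df` with transition width `df = max(0.25 * low, 4)` Hz,
#' unless the band fixes `filter_order`. When the transition band would
#' cross DC (`low < df/2`, the delta band), the filter is designed as a
#' low-pass at `high`: a fractional-hertz high-pass corner is not resolvable
#' on trial-length epochs and is covered by the acquisition high-pass plus
#' per-trial mean removal.
#'
#' @param band A [subband_spec()].
#' @param fs Sampling rate, Hz.
#' @return Numeric coefficient vector of length `N + 1`, with attributes
#'   `order` (N) and `type` (`"pass"` or `"low"`).
#' @export
design_bandpass <- function(band, fs) {
  stopifnot(inherits(band, "subband_spec"))
  if (band$high >= fs / 2) {
    stop("configuration error: band \"", band$name,
         "\" exceeds the Nyquist frequency at fs = ", fs, call. = FALSE)
  }
  df <- band_transition(band$low)
  n_req <- required_order(fs, df)
  N <- band$filter_order %||% n_req
  if (N < n_req) {
    stop("configuration error: filter_order ", N, " too small for the ",
         "transition-width rule (need >= ", n_req, ")", call. = FALSE)
  }
  lowpass_only <- band$low < df / 2
  h <- if (lowpass_only) {
    windowed_sinc(N, 0, band$high, fs)
  } else {
    windowed_sinc(N, band$low, band$high, fs)
  }
  attr(h, "order") <- N
  attr(h, "type") <- if (lowpass_only) "low" else "pass"
  h
}

# Blackman windowed-sinc band-pass (f1 = 0 gives a low-pass), normalized to
# unit gain at the passband center so the response is exactly 0.5 (-6 dB)
# at each cutoff
windowed_sinc <- function(N, f1, f2, fs) {
  n <- 0:N - N / 2
  hi <- ifelse(n == 0, 2 * (f2 - f1) / fs,
               (sin(2 * pi * f2 * n / fs) - sin(2 * pi * f1 * n / fs)) /
                 (pi * n))
  w <- 0.42 - 0.5 * cos(2 * pi * (0:N) / N) + 0.08 * cos(4 * pi * (0:N) / N)
  h <- hi * w
  fc <- (f1 + f2) / 2
  g <- abs(sum(h * exp(-2i * pi * fc * (0:N) / fs)))
  h / g
}

required_order <- function(fs, df) {
  N <- ceiling(5.5 * fs / df)
  if (N %% 2 == 1) N <- N + 1
  as.integer(N)
}

# low-pass designs used by the fixed pipeline stages
design_lowpass <- function(fs, cutoff, df) {
  N <- required_order(fs, df)
  h <- windowed_sinc(N, 0, cutoff, fs)
  attr(h, "order") <- N
  h
}

#' Zero-phase FIR filtering by forward pass and group-delay removal
#'
#' Applies a linear-phase FIR filter in the forward direction on a
#' zero-padded signal, then advances the output by `N/2` samples so the
#' filter's group delay is removed and passband components keep their phase.
#' Output length equals input length; the first and last `N/2` samples are
#' edge-contaminated by the zero padding.
#'
#' @param x Numeric vector, or a matrix filtered column-wise.
#' @param h FIR coefficients (length `N + 1`).
#' @param N Filter order; defaults to `length(h) - 1`.
#' @return Filtered signal, same shape as `x`.
#' @export
filter_zero_phase <- function(x, h, N = length(h) - 1L) {
  if (is.matrix(x)) {
    if (nrow(x) <= N) {
      stop("signal shorter than filter (", nrow(x), " <= ", N, ")",
           call. = FALSE)
    }
    return(fft_filter_mat(x, h, N))
  }
  if (length(x) <= N) {
    stop("signal shorter than filter (", length(x), " <= ", N, ")",
         call. = FALSE)
  }
  drop(fft_filter_mat(matrix(x, ncol = 1L), h, N))
}

# FFT overlap-free convolution of every column of x with h, advanced by N/2
fft_filter_mat <- function(x, h, N = length(h) - 1L) {
  n <- nrow(x)
  nfft <- stats::nextn(n + N, c(2, 3, 5))
  H <- fft(c(h, rep(0, nfft - length(h))))
  X <- mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  y <- Re(mvfft(X * H, inverse = TRUE)) / nfft
  y[(N / 2 + 1):(N / 2 + n), , drop = FALSE]
}

#' Envelope of a narrowband signal via the analytic signal
#'
#' Forms the analytic signal (the signal plus i times its Hilbert transform)
#' with the FFT construction and returns its magnitude, the instantaneous
#' amplitude envelope.
#'
#' @param x Numeric vector, or matrix processed column-wise.
#' @return Non-negative envelope, same shape as `x`.
#' @export
hilbert_envelope <- function(x) {
  if (is.matrix(x)) return(apply_analytic(x))
  drop(apply_analytic(matrix(x, ncol = 1L)))
}

apply_analytic <- function(x) {
  n <- nrow(x)
  if (n == 0L) return(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1L] <- 1; w[n / 2 + 1L] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1L] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  Mod(mvfft(mvfft(x) * w, inverse = TRUE)) / n
}
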