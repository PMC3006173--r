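#' Trial-epoched multichannel LFP container
#'
#' A `trial_set` holds a trials x channels x samples tensor of local field
#' potentials together with per-trial direction labels and alignment
#' metadata. Direction is stored as a class index `0..K-1`; the physical
#' angle of index `i` is `i * 360/K` degrees with 0 degrees along +x,
#' counterclockwise (K = 8 equally spaced center-out targets by default).
#'
#' @param data Numeric array `[n_trials, n_channels, n_samples]`, all finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param labels Integer vector of per-trial direction indices in `[0, K)`.
#' @param alignment Name of the alignment event, `"cue_onset"` or
#'   `"movement_onset"`.
#' @param t0_ms Time of the first sample relative to the alignment event, ms.
#' @param channel_mask Logical per-channel vector, `TRUE` = usable. Defaults
#'   to all usable.
#' @param session_id Integer session identifier.
#' @param K Number of direction classes.
#'
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(data, fs, labels,
                      alignment = "movement_onset",
                      t0_ms = 0,
                      channel_mask = NULL,
                      session_id = 1L,
                      K = 8L) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array [trials, channels, samples]", call. = FALSE)
  }
  channel_mask <- channel_mask %||% rep(TRUE, dim(data)[2L])
  x <- structure(
    list(
      data = data,
      fs = as.numeric(fs),
      labels = as.integer(labels),
      alignment = as.character(alignment),
      t0_ms = as.numeric(t0_ms),
      channel_mask = as.logical(channel_mask),
      session_id = as.integer(session_id),
      K = as.integer(K)
    ),
    class = "trial_set"
  )
  validate_trial_set(x)
}

#' Validate a trial_set's invariants
#'
#' Checks label length and range, positive sampling rate, finiteness of the
#' tensor, and channel-mask length. Called by [trial_set()] and
#' [read_trialset()].
#'
#' @param x A `trial_set`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_trial_set <- function(x) {
  d <- dim(x$data)
  if (length(x$labels) != d[1L]) {
    stop("validation error: labels length (", length(x$labels),
         ") != n_trials (", d[1L], ")", call. = FALSE)
  }
  if (any(x$labels < 0L | x$labels >= x$K)) {
    stop("validation error: labels must lie in [0, K=", x$K, ")", call. = FALSE)
  }
  if (!is.finite(x$fs) || x$fs <= 0) {
    stop("validation error: fs must be > 0", call. = FALSE)
  }
  if (!all(is.finite(x$data))) {
    stop("validation error: data contains non-finite values", call. = FALSE)
  }
  if (length(x$channel_mask) != d[2L]) {
    stop("validation error: channel_mask length (", length(x$channel_mask),
         ") != n_channels (", d[2L], ")", call. = FALSE)
  }
  x
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<trial_set> ", d[1L], " trials x ", d[2L], " channels x ", d[3L],
      " samples @ ", x$fs, " Hz\n", sep = "")
  cat("  alignment: ", x$alignment, " (t0 = ", x$t0_ms, " ms), session ",
      x$session_id, "\n", sep = "")
  cat("  K = ", x$K, " directions; usable channels: ",
      sum(x$channel_mask), "/", d[2L], "\n", sep = "")
  invisible(x)
}

#' @export
dim.trial_set <- function(x) dim(x$data)

#' Subset trials and/or channels of a trial_set
#'
#' @param x A `trial_set`.
#' @param trials Integer indices of trials to keep (default all).
#' @param channels Integer indices of channels to keep (default all).
#' @return A `trial_set` restricted to the selection.
#' @export
subset_trials <- function(x, trials = NULL, channels = NULL) {
  d <- dim(x$data)
  trials <- trials %||% seq_len(d[1L])
  channels <- channels %||% seq_len(d[2L])
  trial_set(
    data = x$data[trials, channels, , drop = FALSE],
    fs = x$fs, labels = x$labels[trials], alignment = x$alignment,
    t0_ms = x$t0_ms, channel_mask = x$channel_mask[channels],
    session_id = x$session_id, K = x$K
  )
}

#' Sorted spike-time container
#'
#' Spike times per unit per trial, in ms relative to the alignment event.
#'
#' @param units List (length `n_units`) of lists (length `n_trials`) of
#'   ascending numeric spike-time vectors, ms.
#' @param labels Integer direction indices per trial, in `[0, K)`.
#' @param alignment Alignment event name.
#' @param session_id Integer session id.
#' @param K Number of direction classes.
#' @return An object of class `spike_set`.
#' @export
spike_set <- function(units, labels, alignment = "movement_onset",
                      session_id = 1L, K = 8L) {
  n_trials <- length(labels)
  for (u in seq_along(units)) {
    if (length(units[[u]]) != n_trials) {
      stop("validation error: unit ", u, " has ", length(units[[u]]),
           " trials, expected ", n_trials, call. = FALSE)
    }
    for (tr in seq_len(n_trials)) {
      st <- units[[u]][[tr]]
      if (is.unsorted(st, strictly = FALSE)) {
        stop("validation error: spike times unsorted (unit ", u,
             ", trial ", tr, ")", call. = FALSE)
      }
    }
  }
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= K)) {
    stop("validation error: labels must lie in [0, K)", call. = FALSE)
  }
  structure(
    list(units = units, n_trials = n_trials, labels = labels,
         alignment = as.character(alignment), session_id = as.integer(session_id),
         K = as.integer(K)),
    class = "spike_set"
  )
}

#' @export
print.spike_set <- function(x, ...) {
  cat("<spike_set> ", length(x$units), " units x ", x$n_trials,
      " trials, aligned to ", x$alignment, "\n", sep = "")
  invisible(x)
}
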