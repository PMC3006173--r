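#' Read and write the on-disk trial container
#'
#' Sessions are stored one per file in a self-describing binary container:
#' an 8-byte magic string (`"LFPTRSET"`), a little-endian uint32 header
#' length, a UTF-8 JSON header (format version, tensor dimensions, `fs`,
#' `alignment`, `t0_ms`, `session_id`, labels, channel mask, spike layout),
#' then the LFP tensor as IEEE float32 in R column-major order over
#' (trial, channel, sample), followed by optional per-unit per-trial float32
#' spike-time arrays. Writing the same content twice produces byte-identical
#' files; reading back recovers the tensor to float32 precision.
#'
#' @param path File path.
#' @param x A `trial_set`.
#' @param spikes Optional `spike_set` stored alongside the LFP tensor.
#' @return `read_trialset()` returns a validated `trial_set`; if the file
#'   carries spikes they are attached as attribute `"spikes"` (a
#'   `spike_set`). `write_trialset()` returns `path` invisibly.
#' @seealso [read_spikeset()] to extract the spike part only.
#' @export
read_trialset <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, "LFPTRSET")) {
    stop("format error: bad magic; not a trial-set container", call. = FALSE)
  }
  nh <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", nh)),
                            simplifyVector = TRUE)
  for (field in c("dims", "fs", "alignment", "t0_ms", "session_id", "labels")) {
    if (is.null(hdr[[field]])) {
      stop("format error: missing required header item \"", field, "\"",
           call. = FALSE)
    }
  }
  d <- as.integer(hdr$dims)
  n <- prod(d)
  dat <- readBin(con, "numeric", n, size = 4L, endian = "little")
  if (length(dat) != n) stop("format error: truncated LFP payload", call. = FALSE)
  ts <- trial_set(
    data = array(dat, dim = d),
    fs = hdr$fs,
    labels = as.integer(hdr$labels),
    alignment = hdr$alignment,
    t0_ms = hdr$t0_ms,
    channel_mask = if (is.null(hdr$channel_mask)) NULL else as.logical(hdr$channel_mask),
    session_id = hdr$session_id,
    K = if (is.null(hdr$K)) 8L else as.integer(hdr$K)
  )
  if (!is.null(hdr$spike_counts)) {
    counts <- hdr$spike_counts       # n_units x n_trials matrix of counts
    counts <- matrix(as.integer(counts), nrow = as.integer(hdr$n_units))
    units <- vector("list", nrow(counts))
    for (u in seq_len(nrow(counts))) {
      units[[u]] <- vector("list", ncol(counts))
      for (tr in seq_len(ncol(counts))) {
        units[[u]][[tr]] <- readBin(con, "numeric", counts[u, tr],
                                    size = 4L, endian = "little")
      }
    }
    attr(ts, "spikes") <- spike_set(units, ts$labels, ts$alignment,
                                    ts$session_id, ts$K)
  }
  ts
}

#' @rdname read_trialset
#' @export
write_trialset <- function(x, path, spikes = NULL) {
  validate_trial_set(x)
  hdr <- list(
    format_version = 1L,
    dims = dim(x$data),
    fs = x$fs,
    alignment = x$alignment,
    t0_ms = x$t0_ms,
    session_id = x$session_id,
    K = x$K,
    labels = x$labels,
    channel_mask = as.integer(x$channel_mask)
  )
  if (!is.null(spikes)) {
    stopifnot(inherits(spikes, "spike_set"))
    hdr$n_units <- length(spikes$units)
    hdr$spike_counts <- vapply(spikes$units,
                               function(u) vapply(u, length, integer(1)),
                               integer(spikes$n_trials))
    # stored as n_units x n_trials after transpose below
    hdr$spike_counts <- t(hdr$spike_counts)
  }
  hj <- charToRaw(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("I/O error: cannot open ", path,
                                           " for writing", call. = FALSE))
  on.exit(close(con))
  writeBin(charToRaw("LFPTRSET"), con)
  writeBin(length(hj), con, size = 4L, endian = "little")
  writeBin(hj, con)
  writeBin(as.numeric(x$data), con, size = 4L, endian = "little")
  if (!is.null(spikes)) {
    for (u in spikes$units) {
      for (st in u) writeBin(as.numeric(st), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname read_trialset
#' @export
read_spikeset <- function(path) {
  ts <- read_trialset(path)
  sp <- attr(ts, "spikes")
  if (is.null(sp)) stop("format error: file carries no spike data", call. = FALSE)
  sp
}

#' Automated line-noise channel screening
#'
#' Flags channels whose mean spectral power within `line_freq` +/- 1 Hz
#' exceeds `ratio_threshold` times their median broadband power, as an
#' automated stand-in for visual artifact screening. Channels already masked
#' unusable stay unusable.
#'
#' @param x A `trial_set`.
#' @param line_freq Mains frequency, Hz (default 60).
#' @param ratio_threshold Line-to-broadband power ratio above which a channel
#'   is flagged (default 10).
#' @return Logical channel mask (`TRUE` = usable).
#' @export
screen_line_noise <- function(x, line_freq = 60, ratio_threshold = 10) {
  stopifnot(inherits(x, "trial_set"))
  if (line_freq >= x$fs / 2) {
    stop("line_freq must be below the Nyquist frequency", call. = FALSE)
  }
  d <- dim(x$data)
  n <- d[3L]
  freqs <- (seq_len(n) - 1) * x$fs / n
  half <- freqs > 0 & freqs <= x$fs / 2
  in_line <- half & abs(freqs - line_freq) <= 1
  mask <- x$channel_mask
  for (ch in seq_len(d[2L])) {
    if (!mask[ch]) next
    # trial-averaged periodogram
    seg <- t(x$data[, ch, , drop = TRUE])
    if (d[1L] == 1L) seg <- matrix(x$data[1, ch, ], ncol = 1L)
    psd <- rowMeans(Mod(mvfft(seg))^2)
    line_power <- mean(psd[in_line])
    broad_power <- median(psd[half])
    if (is.finite(line_power) && is.finite(broad_power) && broad_power > 0 &&
        line_power > ratio_threshold * broad_power) {
      mask[ch] <- FALSE
    }
  }
  mask
}
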