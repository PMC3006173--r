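#' Bin spike times into count series
#'
#' Counts spikes per unit per trial in contiguous `bin_ms` bins over the
#' epoch; 2 ms bins give a 500 Hz-equivalent count series that can be fed to
#' the same sub-band decoding pipeline as LFP. Spikes inside the epoch are
#' conserved exactly.
#'
#' @param s A `spike_set`.
#' @param bin_ms Bin width, ms (default 2).
#' @param epoch_ms `(start, end)` ms relative to the alignment event; the
#'   span must be divisible by `bin_ms`.
#' @return An object of class `binned_spikes`: `counts`
#'   `[n_trials, n_units, n_bins]`, `bin_ms`, `fs_equiv = 1000/bin_ms`,
#'   `labels`, `t0_ms`, `K`.
#' @export
bin_spikes <- function(s, bin_ms = 2, epoch_ms) {
  stopifnot(inherits(s, "spike_set"))
  span <- epoch_ms[2L] - epoch_ms[1L]
  if (span <= 0 || abs(span / bin_ms - round(span / bin_ms)) > 1e-9) {
    stop("epoch span must be a positive multiple of bin_ms", call. = FALSE)
  }
  n_bins <- as.integer(round(span / bin_ms))
  edges <- epoch_ms[1L] + bin_ms * (0:n_bins)
  n_units <- length(s$units)
  counts <- array(0L, dim = c(s$n_trials, n_units, n_bins))
  for (u in seq_len(n_units)) {
    for (tr in seq_len(s$n_trials)) {
      st <- s$units[[u]][[tr]]
      if (is.unsorted(st)) stop("unsorted spike times", call. = FALSE)
      st <- st[st >= edges[1L] & st < edges[n_bins + 1L]]
      if (length(st)) {
        b <- findInterval(st, edges, rightmost.closed = FALSE)
        tab <- tabulate(b, nbins = n_bins)
        counts[tr, u, ] <- tab
      }
    }
  }
  structure(
    list(counts = counts, bin_ms = bin_ms, fs_equiv = 1000 / bin_ms,
         labels = s$labels, t0_ms = epoch_ms[1L], K = s$K,
         session_id = s$session_id, alignment = s$alignment),
    class = "binned_spikes"
  )
}

#' @export
print.binned_spikes <- function(x, ...) {
  d <- dim(x$counts)
  cat("<binned_spikes> ", d[1L], " trials x ", d[2L], " units x ", d[3L],
      " bins of ", x$bin_ms, " ms (", x$fs_equiv, " Hz equivalent)\n",
      sep = "")
  invisible(x)
}

#' Convert binned spikes to a trial_set of count signals
#'
#' @param x A `binned_spikes`.
#' @return A `trial_set` at `fs_equiv` Hz whose "channels" are units.
#' @export
as_trial_set <- function(x) {
  stopifnot(inherits(x, "binned_spikes"))
  trial_set(data = x$counts * 1.0, fs = x$fs_equiv, labels = x$labels,
            alignment = x$alignment, t0_ms = x$t0_ms,
            session_id = x$session_id, K = x$K)
}

#' Decode direction from spike counts with the CSP + ECOC pipeline
#'
#' Treats each unit's 2 ms count series as a 500 Hz signal and runs it
#' through the identical sub-band preprocessing, CSP feature extraction and
#' ECOC classification used for LFP. Each sub-band is evaluated separately
#' and all are reported.
#'
#' @param b A `binned_spikes` (use `bin_ms = 2` for the canonical 500 Hz
#'   series).
#' @param bands Named list of [subband_spec()]s to evaluate (default the
#'   delta band, the most informative for spiking activity; pass
#'   [default_bands()] for all five).
#' @inheritParams cross_validate
#' @return Tibble with one row per band: `band`, `dp`, `rho_t`, and the
#'   full `evaluation_result` in list-column `result`.
#' @export
sua_csp_decode <- function(b, bands = default_bands("delta"),
                           window_ms = NULL, folds = 10L, reps = 10L,
                           seed = 1L, m = 3L, csp_shrinkage = NULL,
                           fld_shrinkage = 0.1) {
  stopifnot(inherits(b, "binned_spikes"))
  if (dim(b$counts)[2L] < 2L) stop("need >= 2 units", call. = FALSE)
  ts <- as_trial_set(b)
  rows <- lapply(names(bands), function(nm) {
    tb <- preprocess_subband(ts, bands[[nm]])
    res <- cross_validate(tb, window_ms = window_ms, folds = folds,
                          reps = reps, seed = seed, K = b$K, m = m,
                          csp_shrinkage = csp_shrinkage,
                          fld_shrinkage = fld_shrinkage)
    tibble::tibble(band = nm, dp = res$dp, rho_t = res$rho_t,
                   result = list(res))
  })
  dplyr::bind_rows(rows)
}

# regularized multi-class LDA on count vectors
rlda_fit <- function(features, labels, K, shrinkage) {
  d <- ncol(features)
  mu <- matrix(0, K, d)
  Sw <- matrix(0, d, d)
  n <- nrow(features)
  for (k in 0:(K - 1L)) {
    idx <- which(labels == k)
    mu[k + 1L, ] <- colMeans(features[idx, , drop = FALSE])
    if (length(idx) > 1L) {
      Sw <- Sw + (length(idx) - 1L) * cov(features[idx, , drop = FALSE])
    }
  }
  Sw <- Sw / (n - K)
  nu <- sum(diag(Sw)) / d
  if (nu <= 0) nu <- 1
  Sreg <- (1 - shrinkage) * Sw + shrinkage * nu * diag(d)
  list(mu = mu, Sinv = solve(Sreg), K = K)
}

rlda_predict <- function(model, features) {
  A <- model$Sinv %*% t(model$mu)                     # d x K
  scores <- features %*% A -
    matrix(colSums(t(model$mu) * A) / 2, nrow(features), model$K, byrow = TRUE)
  apply(scores, 1L, which.max) - 1L
}

#' Regularized-LDA baseline on sliding spike-count windows
#'
#' The classical baseline: spike counts per unit in 200 ms windows stepped
#' by 100 ms, classified with a multi-class linear discriminant whose
#' pooled covariance is shrunk toward a scaled identity, cross-validated
#' with the same stratified scheme as the main decoder.
#'
#' @param s A `spike_set`.
#' @param window_ms Count window length, ms (default 200).
#' @param step_ms Window step, ms (default 100).
#' @param epoch_ms `(start, end)` ms swept by the windows.
#' @param shrinkage Covariance shrinkage in `[0, 1]` (default 0.5).
#' @inheritParams cross_validate
#' @return Tibble with one row per window: `window_start`, `window_end`,
#'   `dp`, `rho_t`.
#' @export
rlda_decode <- function(s, window_ms = 200, step_ms = 100,
                        epoch_ms = c(-1000, 1000), shrinkage = 0.5,
                        folds = 10L, reps = 10L, seed = 1L) {
  stopifnot(inherits(s, "spike_set"))
  if (length(s$units) < 2L) stop("need >= 2 units", call. = FALSE)
  starts <- seq(epoch_ms[1L], epoch_ms[2L] - window_ms, by = step_ms)
  K <- s$K
  labels <- s$labels
  fold_plan <- make_folds(labels, folds, reps, seed)
  rows <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    win <- c(starts[w], starts[w] + window_ms)
    feats <- vapply(s$units, function(u) {
      vapply(u, function(st) sum(st >= win[1L] & st < win[2L]), numeric(1))
    }, numeric(s$n_trials))                             # n_trials x n_units
    dp <- rho <- numeric(0)
    for (r in seq_len(reps)) {
      fold_id <- fold_plan[[r]]
      for (f in seq_len(folds)) {
        test <- which(fold_id == f); train <- which(fold_id != f)
        mdl <- rlda_fit(feats[train, , drop = FALSE], labels[train], K,
                        shrinkage)
        pred <- rlda_predict(mdl, feats[test, , drop = FALSE])
        dp <- c(dp, decoding_power(pred, labels[test]))
        rho <- c(rho, as.numeric(circular_correlation(
          direction_angle(pred, K), direction_angle(labels[test], K))))
      }
    }
    rows[[w]] <- tibble::tibble(window_start = win[1L], window_end = win[2L],
                                dp = mean(dp), rho_t = mean(rho))
  }
  dplyr::bind_rows(rows)
}
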