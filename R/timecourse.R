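#' Sliding-window time course of decoding accuracy
#'
#' Sweeps an analysis window across the epoch and runs the full
#' cross-validated decoder — CSP and FLD refitted per window and per fold —
#' at every position. Two standard protocols: cue-aligned, a 500 ms window
#' first ending at cue onset and stepped in 100 ms increments until it ends
#' 1200 ms after the cue; movement-aligned, a 1000 ms window starting
#' 1400 ms before movement onset stepped in 100 ms increments until it ends
#' 1000 ms after movement onset. The same master seed drives every window,
#' so fold partitions are identical across positions and per-fold series
#' can be summed over windows.
#'
#' @param x A `trial_set`.
#' @param protocol `"movement"`, `"cue"`, or `"custom"` (then give
#'   `window_ms`, `start_ms`, `end_ms`).
#' @param window_ms Window length, ms.
#' @param start_ms Start of the first window, ms relative to alignment.
#' @param step_ms Window step (default 100 ms).
#' @param end_ms Latest allowed window end, ms.
#' @param bands Named list of [subband_spec()]s (default delta + gamma).
#' @inheritParams cross_validate
#' @return A `window_sweep` tibble: `window_start`, `window_end`, `dp`,
#'   `rho_t`, `conf_low`/`conf_high` (95% corrected-t CI of mean rho_t) and
#'   `rate_of_change` (first difference of `rho_t` per 100 ms). Attributes:
#'   `fold_rho` (`J x n_windows` per-fold correlations), `fold_dp`,
#'   `n_train`, `n_test`, `step_ms`.
#' @export
sliding_timecourse <- function(x, protocol = c("movement", "cue", "custom"),
                               window_ms = NULL, start_ms = NULL,
                               step_ms = 100, end_ms = NULL,
                               bands = default_bands(c("delta", "gamma")),
                               folds = 10L, reps = 10L, seed = 1L,
                               m = 3L, csp_shrinkage = NULL,
                               fld_shrinkage = 0.1) {
  protocol <- match.arg(protocol)
  if (protocol == "movement") {
    window_ms <- window_ms %||% 1000; start_ms <- start_ms %||% -1400
    end_ms <- end_ms %||% 1000
  } else if (protocol == "cue") {
    window_ms <- window_ms %||% 500; start_ms <- start_ms %||% -500
    end_ms <- end_ms %||% 1200
  } else if (is.null(window_ms) || is.null(start_ms) || is.null(end_ms)) {
    stop("custom protocol needs window_ms, start_ms and end_ms", call. = FALSE)
  }
  starts <- seq(start_ms, end_ms - window_ms, by = step_ms)
  if (length(starts) == 0L) stop("no window fits the protocol", call. = FALSE)
  banded <- preprocess_bands(x, bands)
  J <- folds * reps
  fold_rho <- matrix(NA_real_, J, length(starts))
  fold_dp <- matrix(NA_real_, J, length(starts))
  rows <- vector("list", length(starts))
  n_train <- n_test <- NA_real_
  for (w in seq_along(starts)) {
    win <- c(starts[w], starts[w] + window_ms)
    res <- tryCatch(
      cross_validate(banded, window_ms = win, folds = folds, reps = reps,
                     seed = seed, K = x$K, m = m,
                     csp_shrinkage = csp_shrinkage,
                     fld_shrinkage = fld_shrinkage),
      error = function(e) {
        stop("window position [", win[1L], ", ", win[2L], ") ms failed: ",
             conditionMessage(e), call. = FALSE)
      })
    fold_rho[, w] <- res$fold_scores$rho_t
    fold_dp[, w] <- res$fold_scores$dp
    n_train <- res$n_train; n_test <- res$n_test
    ci <- corrected_ttest(res$fold_scores$rho_t, 0, res$n_train, res$n_test)
    rows[[w]] <- tibble::tibble(
      window_start = win[1L], window_end = win[2L],
      dp = res$dp, rho_t = res$rho_t,
      conf_low = ci$conf_low, conf_high = ci$conf_high)
  }
  out <- dplyr::bind_rows(rows)
  out$rate_of_change <- c(NA_real_, diff(out$rho_t) * (100 / step_ms))
  out <- tibble::new_tibble(out, class = "window_sweep")
  attr(out, "fold_rho") <- fold_rho
  attr(out, "fold_dp") <- fold_dp
  attr(out, "n_train") <- n_train
  attr(out, "n_test") <- n_test
  attr(out, "step_ms") <- step_ms
  out
}

#' Peak and half-decay of the rate of change of decoding accuracy
#'
#' Summarizes how abruptly the correlation time course rises: the peak of
#' the rate-of-change series, its time, and the first post-peak time at
#' which the rate falls below 50% of the peak (NA when the series never
#' decays below that level).
#'
#' @param sweep A `window_sweep`, or any data frame with `window_end` and
#'   `rate_of_change` columns.
#' @return One-row tibble: `peak_value`, `peak_time`, `half_decay_time`.
#' @export
rate_of_change_summary <- function(sweep) {
  rate <- sweep$rate_of_change
  times <- sweep$window_end
  keep <- !is.na(rate)
  rate <- rate[keep]; times <- times[keep]
  if (length(rate) < 2L) stop("need at least 3 sweep points", call. = FALSE)
  pk <- which.max(rate)
  half <- which(rate < 0.5 * rate[pk] & seq_along(rate) > pk)
  tibble::tibble(
    peak_value = rate[pk], peak_time = times[pk],
    half_decay_time = if (length(half)) times[half[1L]] else NA_real_)
}

#' Test for direction information during the instructed delay
#'
#' Sums the per-fold circular correlations over the sweep windows ending
#' inside the delay period and tests the sum against zero with the
#' corrected t-test: a small but consistently positive correlation across
#' the delay indicates pre-movement information.
#'
#' @param sweep A `window_sweep` from [sliding_timecourse()].
#' @param delay_window_ms `(start, end)` ms; windows whose end falls in
#'   `[start, end]` contribute.
#' @return One-row tibble as [corrected_ttest()], plus `n_windows`.
#' @export
delay_period_test <- function(sweep, delay_window_ms) {
  cols <- which(sweep$window_end >= delay_window_ms[1L] &
                  sweep$window_end <= delay_window_ms[2L])
  if (length(cols) == 0L) stop("no sweep window ends inside the delay period",
                               call. = FALSE)
  fold_rho <- attr(sweep, "fold_rho")
  sums <- rowSums(fold_rho[, cols, drop = FALSE])
  out <- corrected_ttest(sums, 0, attr(sweep, "n_train"),
                         attr(sweep, "n_test"))
  out$n_windows <- length(cols)
  out
}
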