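#' Decoding power
#'
#' Fraction of trials whose predicted class equals the true class.
#'
#' @param pred,actual Equal-length class index vectors.
#' @return A fraction in `[0, 1]`.
#' @export
decoding_power <- function(pred, actual) {
  if (length(pred) != length(actual) || length(pred) == 0L) {
    stop("pred and actual must be equal-length, non-empty", call. = FALSE)
  }
  mean(pred == actual)
}

#' Fisher-Lee circular correlation between two angle sequences
#'
#' T-linear association
#' `rho_T = sum_{i<j} sin(a_i - a_j) sin(b_i - b_j) / sqrt(sum sin^2 * sum sin^2)`,
#' in `[-1, 1]`. Unlike raw accuracy it credits predictions that land near
#' the true direction on the circle. A degenerate sequence (all angles
#' equal on either side) returns 0 with attribute `degenerate = TRUE`
#' rather than an error, so sliding-window series remain plottable.
#'
#' @param pred_angles,actual_angles Equal-length angle vectors, radians,
#'   length >= 3.
#' @return Scalar correlation; attribute `degenerate` flags the 0 fallback.
#' @export
circular_correlation <- function(pred_angles, actual_angles) {
  n <- length(pred_angles)
  if (n != length(actual_angles) || n < 3L) {
    stop("need equal-length angle vectors of length >= 3", call. = FALSE)
  }
  da <- sin(outer(pred_angles, pred_angles, "-"))
  db <- sin(outer(actual_angles, actual_angles, "-"))
  den <- sqrt(sum(da^2) * sum(db^2))
  if (den == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(sum(da * db) / den, degenerate = FALSE)
}

#' Nadeau-Bengio corrected t-test for cross-validation scores
#'
#' Repeated cross-validation scores are positively correlated across folds
#' because training sets overlap; the naive t-test is anti-conservative.
#' The corrected test inflates the variance of the mean difference to
#' `sigma^2 * (1/J + n_test/n_train)` with `J` scores and uses `J - 1`
#' degrees of freedom.
#'
#' @param scores_a Per-fold score vector (length `J = folds x reps`).
#' @param scores_b Second score vector of equal length, or a scalar null
#'   value (default 0).
#' @param n_train,n_test Training and test set sizes of one fold.
#' @return One-row tibble: `estimate` (mean difference), `statistic`,
#'   `p_value` (two-sided), `df`, `conf_low`, `conf_high` (95% CI).
#' @export
corrected_ttest <- function(scores_a, scores_b = 0, n_train, n_test) {
  J <- length(scores_a)
  if (J < 2L) stop("need at least 2 scores", call. = FALSE)
  d <- scores_a - scores_b
  md <- mean(d)
  v <- var(d)
  if (v == 0) {
    t_stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
    return(tibble::tibble(estimate = md, statistic = t_stat, p_value = p,
                          df = J - 1, conf_low = md, conf_high = md))
  }
  se <- sqrt(v * (1 / J + n_test / n_train))
  t_stat <- md / se
  p <- 2 * pt(-abs(t_stat), df = J - 1)
  ci <- md + c(-1, 1) * qt(0.975, df = J - 1) * se
  tibble::tibble(estimate = md, statistic = t_stat, p_value = p, df = J - 1,
                 conf_low = ci[1L], conf_high = ci[2L])
}

# deterministic seed scoping
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# stratified fold assignment: list over reps of integer fold id per trial
make_folds <- function(labels, folds, reps, seed) {
  counts <- tabulate(labels + 1L, nbins = max(labels) + 1L)
  if (any(counts[counts > 0] < folds)) {
    stop("stratification error: every class needs >= ", folds, " trials",
         call. = FALSE)
  }
  with_seed(seed, {
    lapply(seq_len(reps), function(r) {
      fold_id <- integer(length(labels))
      for (k in sort(unique(labels))) {
        idx <- sample(which(labels == k))
        fold_id[idx] <- rep_len(seq_len(folds), length(idx))
      }
      fold_id
    })
  })
}

new_evaluation_result <- function(dp, rho_t, confusion, fold_scores, seed, K,
                                  n_train, n_test) {
  structure(
    list(dp = dp, rho_t = rho_t, confusion = confusion,
         fold_scores = fold_scores, seed = seed, K = K,
         n_train = n_train, n_test = n_test),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result> DP = ", round(x$dp, 3), ", rho_T = ",
      round(x$rho_t, 3), " (", nrow(x$fold_scores), " fold scores, K = ",
      x$K, ")\n", sep = "")
  invisible(x)
}

#' Repeated stratified cross-validation of the direction decoder
#'
#' 10x10-fold stratified cross-validation by default: in each of `reps`
#' repetitions the trials of every class are partitioned into `folds`
#' folds; the whole pipeline — CSP covariances, spatial filters and FLDs —
#' is fitted inside each fold's training partition only, then the held-out
#' trials are decoded. Reported decoding power and circular correlation are
#' the means over all `folds x reps` scores.
#'
#' @inheritParams ecoc_fit
#' @param folds,reps Cross-validation geometry (default 10 x 10).
#' @param seed Master seed controlling all fold randomness.
#' @return An `evaluation_result`: mean `dp` and `rho_t`, the pooled `K x K`
#'   confusion matrix (rows = actual, columns = predicted, counts over all
#'   repetitions), a `fold_scores` tibble (rep, fold, dp, rho_t), fold
#'   sizes and the seed.
#' @export
cross_validate <- function(banded, labels = NULL, window_ms = NULL,
                           folds = 10L, reps = 10L, seed = 1L, K = NULL,
                           m = 3L, csp_shrinkage = NULL, fld_shrinkage = 0.1) {
  if (inherits(banded, "subband_tensor")) banded <- list(banded)
  labels <- labels %||% banded[[1L]]$labels
  K <- K %||% (banded[[1L]]$K %||% 8L)
  window <- if (is.null(window_ms)) NULL else window_samples(banded[[1L]], window_ms)
  covs_list <- lapply(banded, trial_covariances, window = window)
  cross_validate_cov(covs_list, labels, folds = folds, reps = reps,
                     seed = seed, K = K, m = m,
                     csp_shrinkage = csp_shrinkage,
                     fld_shrinkage = fld_shrinkage)
}

cross_validate_cov <- function(covs_list, labels, folds = 10L, reps = 10L,
                               seed = 1L, K = 8L, m = 3L,
                               csp_shrinkage = NULL, fld_shrinkage = 0.1) {
  fold_plan <- make_folds(labels, folds, reps, seed)
  confusion <- matrix(0L, K, K,
                      dimnames = list(actual = 0:(K - 1), predicted = 0:(K - 1)))
  rows <- vector("list", folds * reps)
  n_tr <- n_te <- numeric(0)
  i <- 0L
  for (r in seq_len(reps)) {
    fold_id <- fold_plan[[r]]
    for (f in seq_len(folds)) {
      test <- which(fold_id == f)
      train <- which(fold_id != f)
      covs_train <- lapply(covs_list,
                           function(a) a[, , train, drop = FALSE])
      model <- ecoc_fit_cov(covs_train, labels[train], K = K, m = m,
                            csp_shrinkage = csp_shrinkage,
                            fld_shrinkage = fld_shrinkage)
      pred <- ecoc_predict_cov(covs_list, model, idx = test)
      actual <- labels[test]
      for (j in seq_along(test)) {
        confusion[actual[j] + 1L, pred[j] + 1L] <-
          confusion[actual[j] + 1L, pred[j] + 1L] + 1L
      }
      i <- i + 1L
      rows[[i]] <- tibble::tibble(
        rep = r, fold = f,
        dp = decoding_power(pred, actual),
        rho_t = as.numeric(circular_correlation(direction_angle(pred, K),
                                                direction_angle(actual, K)))
      )
      n_tr <- c(n_tr, length(train)); n_te <- c(n_te, length(test))
    }
  }
  fold_scores <- dplyr::bind_rows(rows)
  new_evaluation_result(
    dp = mean(fold_scores$dp), rho_t = mean(fold_scores$rho_t),
    confusion = confusion, fold_scores = fold_scores, seed = seed, K = K,
    n_train = mean(n_tr), n_test = mean(n_te)
  )
}

# concatenate subband tensors (same band/channels) across sessions
bind_trials <- function(tensors) {
  ref <- tensors[[1L]]
  for (tb in tensors[-1L]) {
    if (!identical(tb$channels, ref$channels)) {
      stop("channel mismatch across sessions", call. = FALSE)
    }
    if (dim(tb$data)[3L] != dim(ref$data)[3L]) {
      stop("epoch length mismatch across sessions", call. = FALSE)
    }
  }
  dat <- do.call(rbind, lapply(tensors, function(tb) {
    d <- dim(tb$data)
    matrix(tb$data, d[1L], d[2L] * d[3L])
  }))
  n <- sum(vapply(tensors, function(tb) dim(tb$data)[1L], integer(1)))
  ref$data <- array(dat, dim = c(n, dim(ref$data)[2L], dim(ref$data)[3L]))
  ref$labels <- unlist(lapply(tensors, function(tb) tb$labels))
  ref
}

#' Cross-session training and testing
#'
#' Fits the decoder once on the pooled training sessions and evaluates it
#' once on the pooled test sessions — no trial of a test session ever
#' enters training. Channel masks must agree across sessions.
#'
#' @param train,test A `trial_set` or list of them.
#' @param bands Named list of [subband_spec()]s.
#' @param window_ms Analysis window, ms relative to alignment.
#' @inheritParams cross_validate
#' @return An `evaluation_result` whose `fold_scores` has a single row.
#' @export
cross_session_validate <- function(train, test,
                                   bands = default_bands(c("delta", "gamma")),
                                   window_ms = NULL, K = NULL, m = 3L,
                                   csp_shrinkage = NULL, fld_shrinkage = 0.1) {
  if (inherits(train, "trial_set")) train <- list(train)
  if (inherits(test, "trial_set")) test <- list(test)
  masks <- lapply(c(train, test), function(s) s$channel_mask)
  if (!all(vapply(masks, identical, logical(1), y = masks[[1L]]))) {
    stop("channel mismatch: sessions must share the channel set", call. = FALSE)
  }
  K <- K %||% train[[1L]]$K
  banded_tr <- lapply(bands, function(b) {
    bind_trials(lapply(train, preprocess_subband, band = b))
  })
  banded_te <- lapply(bands, function(b) {
    bind_trials(lapply(test, preprocess_subband, band = b))
  })
  model <- ecoc_fit(banded_tr, window_ms = window_ms, K = K, m = m,
                    csp_shrinkage = csp_shrinkage,
                    fld_shrinkage = fld_shrinkage)
  window <- if (is.null(window_ms)) NULL else window_samples(banded_te[[1L]], window_ms)
  covs_te <- lapply(banded_te, trial_covariances, window = window)
  pred <- ecoc_predict_cov(covs_te, model)
  actual <- banded_te[[1L]]$labels
  confusion <- matrix(0L, K, K,
                      dimnames = list(actual = 0:(K - 1), predicted = 0:(K - 1)))
  for (j in seq_along(actual)) {
    confusion[actual[j] + 1L, pred[j] + 1L] <-
      confusion[actual[j] + 1L, pred[j] + 1L] + 1L
  }
  dp <- decoding_power(pred, actual)
  rho <- as.numeric(circular_correlation(direction_angle(pred, K),
                                         direction_angle(actual, K)))
  new_evaluation_result(
    dp = dp, rho_t = rho, confusion = confusion,
    fold_scores = tibble::tibble(rep = 1L, fold = 1L, dp = dp, rho_t = rho),
    seed = NA_integer_, K = K,
    n_train = length(banded_tr[[1L]]$labels), n_test = length(actual)
  )
}

#' Decoding accuracy as a function of channel and trial counts
#'
#' Channel curves draw random channel subsets with replacement (the full
#' channel count uses every channel exactly once, so the curve's endpoint
#' equals the full evaluation) and rerun the cross-validated decoder per
#' subset; trial curves draw balanced per-class trial subsets. Reported one
#' row per (curve, count, draw); the per-count mean is a `dplyr::summarise`
#' away.
#'
#' @param x A `trial_set`.
#' @param channel_counts Integer vector of channel subset sizes (`NULL` to
#'   skip).
#' @param trial_counts Integer vector of per-class trial counts (`NULL` to
#'   skip; each must be >= `folds`).
#' @param draws Random draws per count.
#' @param bands Named list of [subband_spec()]s.
#' @inheritParams cross_validate
#' @return Tibble with columns `curve` ("channels" or "trials"), `count`,
#'   `draw`, `dp`, `rho_t`.
#' @export
subset_curves <- function(x, channel_counts = NULL, trial_counts = NULL,
                          draws = 5L, seed = 1L,
                          bands = default_bands(c("delta", "gamma")),
                          window_ms = NULL, folds = 10L, reps = 2L,
                          m = 3L, csp_shrinkage = NULL, fld_shrinkage = 0.1) {
  banded <- preprocess_bands(x, bands)
  C <- dim(banded[[1L]]$data)[2L]
  labels <- banded[[1L]]$labels
  per_class <- min(tabulate(labels + 1L, nbins = x$K))
  if (!is.null(channel_counts) && any(channel_counts > C)) {
    stop("channel count exceeds the ", C, " usable channels", call. = FALSE)
  }
  if (!is.null(trial_counts) && any(trial_counts > per_class)) {
    stop("trial count exceeds the ", per_class,
         " trials available per class", call. = FALSE)
  }
  rows <- list()
  draw_seeds <- with_seed(seed, sample.int(2^30, draws * 2L))
  for (ci in seq_along(channel_counts)) {
    nc <- channel_counts[ci]
    for (dr in seq_len(draws)) {
      chans <- if (nc == C) seq_len(C) else {
        with_seed(draw_seeds[dr] + ci, sample.int(C, nc, replace = TRUE))
      }
      sub <- lapply(banded, function(tb) {
        tb$data <- tb$data[, chans, , drop = FALSE]
        tb$channels <- tb$channels[chans]
        tb
      })
      res <- cross_validate(sub, window_ms = window_ms, folds = folds,
                            reps = reps, seed = seed, K = x$K, m = m,
                            csp_shrinkage = csp_shrinkage %||% 0.05,
                            fld_shrinkage = fld_shrinkage)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        curve = "channels", count = nc, draw = dr,
        dp = res$dp, rho_t = res$rho_t)
    }
  }
  for (ti in seq_along(trial_counts)) {
    nt <- trial_counts[ti]
    for (dr in seq_len(draws)) {
      idx <- with_seed(draw_seeds[draws + dr] + ti, {
        unlist(lapply(0:(x$K - 1L), function(k) {
          sample(which(labels == k), nt)
        }))
      })
      sub <- lapply(banded, function(tb) {
        tb$data <- tb$data[idx, , , drop = FALSE]
        tb$labels <- tb$labels[idx]
        tb
      })
      res <- cross_validate(sub, window_ms = window_ms, folds = folds,
                            reps = reps, seed = seed, K = x$K, m = m,
                            csp_shrinkage = csp_shrinkage,
                            fld_shrinkage = fld_shrinkage)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        curve = "trials", count = nt, draw = dr,
        dp = res$dp, rho_t = res$rho_t)
    }
  }
  dplyr::bind_rows(rows)
}
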