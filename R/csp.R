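#' Per-trial channel covariances over an analysis window
#'
#' Centered channel-by-channel covariance of each trial, computed over the
#' given sample window. These per-trial matrices are the sufficient
#' statistics for both CSP fitting (after trace normalization and
#' class-averaging) and log-variance features.
#'
#' @param x A `subband_tensor`.
#' @param window Integer sample indices (see [window_samples()]); default
#'   all samples.
#' @return Array `[C, C, n_trials]`.
#' @export
trial_covariances <- function(x, window = NULL) {
  stopifnot(inherits(x, "subband_tensor"))
  d <- dim(x$data)
  window <- window %||% seq_len(d[3L])
  if (length(window) < 2L) stop("window length must be >= 2", call. = FALSE)
  out <- array(0, dim = c(d[2L], d[2L], d[1L]))
  for (tr in seq_len(d[1L])) {
    seg <- x$data[tr, , window, drop = TRUE]
    if (d[2L] == 1L) seg <- matrix(x$data[tr, 1L, window], nrow = 1L)
    seg <- seg - rowMeans(seg)
    out[, , tr] <- tcrossprod(seg) / (length(window) - 1L)
  }
  out
}

#' Class-conditional spatial covariance
#'
#' Averages per-trial channel covariances over the trials of one contrast
#' side. Each trial's covariance is normalized by its trace before
#' averaging, so trials contribute spatial pattern rather than amplitude;
#' optional shrinkage pulls the average toward a scaled identity:
#' `(1 - gamma) * Sigma + gamma * (tr(Sigma)/C) * I`.
#'
#' @param x A `subband_tensor`, or an array `[C, C, n_trials]` of per-trial
#'   covariances from [trial_covariances()].
#' @param trial_indices Trials to average over (>= 2).
#' @param window Sample window (used when `x` is a tensor).
#' @param shrinkage Shrinkage weight in `[0, 1]`.
#' @param trace_normalize Normalize each trial's covariance by its trace
#'   before averaging (default `TRUE`).
#' @param class_label Optional identifier stored in the result.
#' @return An object of class `cov_estimate`: `sigma`, `class_label`,
#'   `n_trials`, `shrinkage`.
#' @export
class_covariance <- function(x, trial_indices = NULL, window = NULL,
                             shrinkage = 0, trace_normalize = TRUE,
                             class_label = NA) {
  covs <- if (is.array(x) && length(dim(x)) == 3L && !inherits(x, "subband_tensor")) {
    x
  } else {
    trial_covariances(x, window)
  }
  trial_indices <- trial_indices %||% seq_len(dim(covs)[3L])
  if (length(trial_indices) < 2L) {
    stop("estimation error: need >= 2 trials per class", call. = FALSE)
  }
  sigma <- average_covariances(covs, trial_indices, shrinkage, trace_normalize)
  structure(list(sigma = sigma, class_label = class_label,
                 n_trials = length(trial_indices), shrinkage = shrinkage),
            class = "cov_estimate")
}

average_covariances <- function(covs, idx, shrinkage, trace_normalize = TRUE) {
  C <- dim(covs)[1L]
  flat <- matrix(covs[, , idx], C * C, length(idx))
  if (trace_normalize) {
    tr <- colSums(flat[seq(1L, C * C, by = C + 1L), , drop = FALSE])
    flat <- sweep(flat, 2L, tr, "/")
  }
  sigma <- matrix(rowMeans(flat), C, C)
  sigma <- (sigma + t(sigma)) / 2
  if (shrinkage > 0) {
    sigma <- (1 - shrinkage) * sigma +
      shrinkage * (sum(diag(sigma)) / C) * diag(C)
  }
  sigma
}

#' Fit Common Spatial Patterns filters
#'
#' Solves the generalized eigenproblem `Sigma1 w = lambda (Sigma1 + Sigma2) w`
#' by whitening the composite covariance: eigenvalues `lambda` lie in
#' `[0, 1]` and give the fraction of composite variance captured for class 1,
#' so the leading filters maximize class-1 variance while minimizing
#' class-2 variance and the trailing filters do the reverse. Columns are
#' scaled so that `W' (Sigma1 + Sigma2) W = I`, ordered by descending
#' eigenvalue, and sign-fixed so each column's largest-magnitude element is
#' positive. The `m` leading plus `m` trailing filters are selected for
#' feature extraction (m = 3 gives the canonical six features per band).
#'
#' @param sigma1,sigma2 `cov_estimate`s or plain symmetric matrices.
#' @param m Number of filters kept from each end of the spectrum; clamped
#'   to `floor(C/2)` when the channel count is small.
#' @param band_name,contrast_id Optional identifiers stored in the model.
#' @return An object of class `csp_model`: `W` (C x C filters in columns),
#'   `eigenvalues` (descending), `selected` (2m column indices), `m`,
#'   `band_name`, `contrast_id`.
#' @export
csp_fit <- function(sigma1, sigma2, m = 3L, band_name = NA, contrast_id = NA) {
  S1 <- if (inherits(sigma1, "cov_estimate")) sigma1$sigma else sigma1
  S2 <- if (inherits(sigma2, "cov_estimate")) sigma2$sigma else sigma2
  stopifnot(identical(dim(S1), dim(S2)))
  C <- nrow(S1)
  if (C < 2L) stop("need at least 2 channels", call. = FALSE)
  # with few channels the 3+3 selection cannot exceed the spectrum: clamp
  m <- min(as.integer(m), C %/% 2L)
  Sc <- (S1 + S2 + t(S1) + t(S2)) / 2
  ec <- eigen(Sc, symmetric = TRUE)
  tol <- max(ec$values) * 1e-10
  if (min(ec$values) < tol) {
    stop("composite covariance is singular or near-singular; ",
         "increase the covariance shrinkage", call. = FALSE)
  }
  P <- ec$vectors %*% (t(ec$vectors) / sqrt(ec$values))
  A <- P %*% ((S1 + t(S1)) / 2) %*% t(P)
  ea <- eigen((A + t(A)) / 2, symmetric = TRUE)
  W <- t(P) %*% ea$vectors
  lambda <- pmin(pmax(ea$values, 0), 1)
  # deterministic sign: largest-magnitude element of each filter positive
  for (j in seq_len(C)) {
    if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  }
  structure(
    list(W = W, eigenvalues = lambda,
         selected = c(seq_len(m), seq.int(C - m + 1L, C)),
         m = as.integer(m), band_name = band_name, contrast_id = contrast_id),
    class = "csp_model"
  )
}

#' @export
print.csp_model <- function(x, ...) {
  cat("<csp_model> ", nrow(x$W), " channels, m = ", x$m,
      "; leading/trailing eigenvalues: ",
      paste(signif(head(x$eigenvalues, x$m), 3), collapse = ", "), " | ",
      paste(signif(tail(x$eigenvalues, x$m), 3), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Project a single trial through selected CSP filters
#'
#' @param trial Matrix `[C, n]` of multichannel samples.
#' @param model A `csp_model`.
#' @param selected Column indices of `model$W` to use; defaults to the
#'   model's selection.
#' @return Matrix `[length(selected), n]`, row j the filter-j projection.
#' @export
csp_project <- function(trial, model, selected = model$selected) {
  if (nrow(trial) != nrow(model$W)) {
    stop("dimension mismatch: trial has ", nrow(trial),
         " channels, model expects ", nrow(model$W), call. = FALSE)
  }
  crossprod(model$W[, selected, drop = FALSE], trial)
}

#' Log-variance feature vector of projected data
#'
#' The feature of each projected component is the natural log of its sample
#' variance over the analysis window; the log transform symmetrizes the
#' skewed variance distribution.
#'
#' @param projected Matrix `[2m, n]` from [csp_project()].
#' @param window Sample indices to use; default all.
#' @return Numeric feature vector of length `nrow(projected)`.
#' @export
log_variance_features <- function(projected, window = NULL) {
  window <- window %||% seq_len(ncol(projected))
  if (length(window) < 2L) stop("window length must be >= 2", call. = FALSE)
  v <- apply(projected[, window, drop = FALSE], 1L, var)
  if (any(v <= 0)) {
    stop("degenerate projection: zero variance component", call. = FALSE)
  }
  log(v)
}

# log-variance features for many trials straight from per-trial covariances:
# feature_j(trial i) = log( w_j' S_i w_j ), computed as one matrix product
cov_log_features <- function(covs, W_sel, idx = NULL) {
  C <- dim(covs)[1L]
  idx <- idx %||% seq_len(dim(covs)[3L])
  V <- apply(W_sel, 2L, function(w) as.numeric(tcrossprod(w)))  # C^2 x 2m
  flat <- matrix(covs[, , idx], C * C, length(idx))
  q <- crossprod(flat, V)                                       # n x 2m
  if (any(q <= 0)) q[q <= 0] <- .Machine$double.xmin
  log(q)
}
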