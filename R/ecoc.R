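#' Enumerate the binary direction contrasts
#'
#' Builds the redundant contrast set for K equally spaced directions: every
#' unordered pair of single directions, then every contiguous group of 2 to
#' K/2 directions against its diametrically opposite group. A contrast and
#' its side-swapped twin count once. For K = 8 this yields 28 pairwise plus
#' 12 group contrasts, L = 40 binary classifiers in total. Order is
#' deterministic: pairs lexicographically, then groups by size and start
#' index.
#'
#' @param K Even class count >= 4.
#' @return A list of contrasts; each is a list with `positive_set` and
#'   `negative_set` (0-based direction indices), `kind` (`"pair"` or
#'   `"group"`) and `id`.
#' @export
enumerate_contrasts <- function(K = 8L) {
  K <- as.integer(K)
  if (K < 4L || K %% 2L != 0L) {
    stop("unsupported configuration: K must be even and >= 4", call. = FALSE)
  }
  contrasts <- list()
  for (i in 0:(K - 2L)) {
    for (j in (i + 1L):(K - 1L)) {
      contrasts[[length(contrasts) + 1L]] <-
        list(positive_set = i, negative_set = j, kind = "pair")
    }
  }
  seen <- character(0)
  for (size in 2:(K %/% 2L)) {
    for (start in 0:(K - 1L)) {
      g <- (start + 0:(size - 1L)) %% K
      opp <- (g + K %/% 2L) %% K
      key_fwd <- paste(paste(sort(g), collapse = ","),
                       paste(sort(opp), collapse = ","), sep = "|")
      key_rev <- paste(paste(sort(opp), collapse = ","),
                       paste(sort(g), collapse = ","), sep = "|")
      if (key_fwd %in% seen || key_rev %in% seen) next
      seen <- c(seen, key_fwd)
      contrasts[[length(contrasts) + 1L]] <-
        list(positive_set = sort(g), negative_set = sort(opp), kind = "group")
    }
  }
  for (l in seq_along(contrasts)) contrasts[[l]]$id <- l
  contrasts
}

#' Build the ECOC code matrix
#'
#' Entry `m[k, l]` is +1 when class `k - 1` belongs to contrast l's positive
#' set, -1 when it belongs to the negative set, and 0 when the contrast does
#' not involve the class. For the canonical 8-direction scheme the matrix is
#' 8 x 40.
#'
#' @param contrasts Output of [enumerate_contrasts()].
#' @param K Class count.
#' @return Integer matrix `[K, L]` with entries in `{-1, 0, 1}`.
#' @export
build_code_matrix <- function(contrasts, K = 8L) {
  M <- matrix(0L, nrow = K, ncol = length(contrasts))
  for (l in seq_along(contrasts)) {
    M[contrasts[[l]]$positive_set + 1L, l] <- 1L
    M[contrasts[[l]]$negative_set + 1L, l] <- -1L
  }
  M
}

#' Fit a Fisher linear discriminant
#'
#' Weight vector proportional to the regularized pooled within-class
#' covariance inverse times the class-mean difference,
#' `w = (Sw + gamma * (tr(Sw)/d) * I)^-1 (mu+ - mu-)`, with bias at the
#' midpoint of the projected means so the margin of the positive class mean
#' is positive.
#'
#' @param features Matrix `[n, d]`.
#' @param y Labels in `{-1, +1}`.
#' @param shrinkage Regularization weight `gamma >= 0`.
#' @return An object of class `fld`: `w`, `b`.
#' @export
fld_fit <- function(features, y, shrinkage = 0.1) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n <= 2L) stop("need more than 2 training samples", call. = FALSE)
  pos <- y > 0
  if (all(pos) || all(!pos)) {
    stop("single-class input: both classes must be present", call. = FALSE)
  }
  d <- ncol(features)
  mu_p <- colMeans(features[pos, , drop = FALSE])
  mu_n <- colMeans(features[!pos, , drop = FALSE])
  Sp <- cov(features[pos, , drop = FALSE])
  Sn <- cov(features[!pos, , drop = FALSE])
  np <- sum(pos); nn <- n - np
  Sw <- ((np - 1) * Sp + (nn - 1) * Sn) / (n - 2)
  nu <- sum(diag(Sw)) / d
  if (nu <= 0) nu <- 1
  w <- solve(Sw + shrinkage * nu * diag(d), mu_p - mu_n)
  b <- sum(w * (mu_p + mu_n)) / 2
  structure(list(w = as.numeric(w), b = as.numeric(b)), class = "fld")
}

#' Signed FLD margin
#'
#' @param model An `fld`.
#' @param feature Feature vector (or matrix `[n, d]` for many samples).
#' @return `w' f - b`; positive favors the contrast's positive side.
#' @export
fld_margin <- function(model, feature) {
  if (is.matrix(feature)) {
    if (ncol(feature) != length(model$w)) {
      stop("dimension mismatch: ", ncol(feature), " features, model expects ",
           length(model$w), call. = FALSE)
    }
    return(as.numeric(feature %*% model$w - model$b))
  }
  if (length(feature) != length(model$w)) {
    stop("dimension mismatch: ", length(feature), " features, model expects ",
         length(model$w), call. = FALSE)
  }
  sum(model$w * feature) - model$b
}

# default CSP shrinkage: regularize when channels outnumber the smaller
# contrast side (rank-deficient average covariance)
auto_csp_shrinkage <- function(C, n_pos, n_neg) {
  if (C > min(n_pos, n_neg)) 0.05 else 0
}

#' Fit the full CSP + FLD + ECOC direction decoder
#'
#' For every contrast of the redundant scheme, one CSP model per sub-band is
#' fitted on the contrast's trials (group sides pool their member classes),
#' the 2m log-variance features per band are concatenated across bands, and
#' one Fisher discriminant is trained on them. Deterministic given data and
#' configuration.
#'
#' @param banded A `subband_tensor` or (named) list of them sharing trial
#'   order; features are concatenated across bands.
#' @param labels Direction indices per trial; taken from the first tensor
#'   when `NULL`.
#' @param window_ms Analysis window `(start, end)` ms relative to the
#'   alignment event; `NULL` uses the whole epoch.
#' @param K Class count.
#' @param m CSP filters kept per spectral end (default 3, i.e. six features
#'   per band per contrast).
#' @param csp_shrinkage Covariance shrinkage; `NULL` = 0.05 when channels
#'   outnumber the smaller contrast side, else 0.
#' @param fld_shrinkage FLD shrinkage (default 0.1).
#' @return An object of class `ecoc_model`.
#' @export
ecoc_fit <- function(banded, labels = NULL, window_ms = NULL, K = NULL,
                     m = 3L, csp_shrinkage = NULL, fld_shrinkage = 0.1) {
  if (inherits(banded, "subband_tensor")) banded <- list(banded)
  labels <- labels %||% banded[[1L]]$labels
  K <- K %||% (banded[[1L]]$K %||% 8L)
  window <- if (is.null(window_ms)) NULL else window_samples(banded[[1L]], window_ms)
  covs_list <- lapply(banded, trial_covariances, window = window)
  model <- ecoc_fit_cov(covs_list, labels, K = K, m = m,
                        csp_shrinkage = csp_shrinkage,
                        fld_shrinkage = fld_shrinkage,
                        band_names = vapply(banded, function(b) b$band$name,
                                            character(1)))
  model$window_ms <- window_ms
  model$bands <- lapply(banded, function(b) b$band)
  model$channels <- banded[[1L]]$channels
  model
}

# core trainer on per-band per-trial covariance arrays
ecoc_fit_cov <- function(covs_list, labels, K = 8L, m = 3L,
                         csp_shrinkage = NULL, fld_shrinkage = 0.1,
                         contrasts = NULL, band_names = NULL) {
  counts <- tabulate(labels + 1L, nbins = K)
  if (any(counts < 2L)) {
    stop("training error: class ", which(counts < 2L)[1L] - 1L,
         " has fewer than 2 trials", call. = FALSE)
  }
  contrasts <- contrasts %||% enumerate_contrasts(K)
  M <- build_code_matrix(contrasts, K)
  C <- dim(covs_list[[1L]])[1L]
  per_contrast <- vector("list", length(contrasts))
  for (l in seq_along(contrasts)) {
    ct <- contrasts[[l]]
    pos_idx <- which(labels %in% ct$positive_set)
    neg_idx <- which(labels %in% ct$negative_set)
    gamma <- csp_shrinkage %||%
      auto_csp_shrinkage(C, length(pos_idx), length(neg_idx))
    csps <- vector("list", length(covs_list))
    feats <- NULL
    for (b in seq_along(covs_list)) {
      covs <- covs_list[[b]]
      S1 <- average_covariances(covs, pos_idx, gamma)
      S2 <- average_covariances(covs, neg_idx, gamma)
      cm <- csp_fit(S1, S2, m = m,
                    band_name = if (is.null(band_names)) b else band_names[b],
                    contrast_id = l)
      csps[[b]] <- cm
      fb <- cov_log_features(covs, cm$W[, cm$selected, drop = FALSE],
                             c(pos_idx, neg_idx))
      feats <- if (is.null(feats)) fb else cbind(feats, fb)
    }
    y <- c(rep(1, length(pos_idx)), rep(-1, length(neg_idx)))
    per_contrast[[l]] <- list(csp = csps,
                              fld = fld_fit(feats, y, fld_shrinkage))
  }
  structure(
    list(contrasts = contrasts, M = M, K = as.integer(K), m = as.integer(m),
         per_contrast = per_contrast, fld_shrinkage = fld_shrinkage,
         band_names = band_names),
    class = "ecoc_model"
  )
}

#' @export
print.ecoc_model <- function(x, ...) {
  cat("<ecoc_model> K = ", x$K, " directions, L = ", length(x$contrasts),
      " contrasts (", sum(vapply(x$contrasts, function(ct) ct$kind, "") == "pair"),
      " pair + ", sum(vapply(x$contrasts, function(ct) ct$kind, "") == "group"),
      " group), ", length(x$per_contrast[[1L]]$csp), " band(s), m = ", x$m,
      "\n", sep = "")
  invisible(x)
}

#' ECOC fusion of contrast margins into a class decision
#'
#' Margins are oriented positive toward each contrast's positive set, so the
#' score of class k is `s_k = -sum_l m[k, l] * y_l`; the predicted class is
#' `argmin_k s_k` (the row of the code matrix most consistent with the
#' margin vector), ties broken by the lowest class index.
#'
#' @param margins Numeric vector of L contrast margins, or a `[n, L]`
#'   matrix.
#' @param M Code matrix `[K, L]`.
#' @return Predicted 0-based class index (vector for matrix input).
#' @export
ecoc_decide <- function(margins, M) {
  if (!is.matrix(margins)) margins <- matrix(margins, nrow = 1L)
  if (ncol(margins) != ncol(M)) {
    stop("dimension mismatch: ", ncol(margins), " margins for ", ncol(M),
         " contrasts", call. = FALSE)
  }
  scores <- -margins %*% t(M)           # n x K
  apply(scores, 1L, which.min) - 1L
}

#' Predict the direction of one trial
#'
#' Projects the trial's per-band data through every contrast's CSP filters,
#' computes log-variance features, evaluates the FLD margins and fuses them
#' with [ecoc_decide()].
#'
#' @param trial A `[C, n]` matrix, or a list of such matrices (one per band,
#'   in the model's band order).
#' @param model An `ecoc_model` from [ecoc_fit()].
#' @return Predicted 0-based class index.
#' @export
ecoc_predict <- function(trial, model) {
  if (is.matrix(trial)) trial <- list(trial)
  n_bands <- length(model$per_contrast[[1L]]$csp)
  if (length(trial) != n_bands) {
    stop("dimension mismatch: model expects ", n_bands, " band(s)",
         call. = FALSE)
  }
  y <- vapply(seq_along(model$contrasts), function(l) {
    pc <- model$per_contrast[[l]]
    f <- unlist(lapply(seq_len(n_bands), function(b) {
      log_variance_features(csp_project(trial[[b]], pc$csp[[b]]))
    }))
    fld_margin(pc$fld, f)
  }, numeric(1))
  as.integer(ecoc_decide(y, model$M))
}

# batch margins for trials given per-band covariance arrays
ecoc_margins_cov <- function(covs_list, model, idx = NULL) {
  idx <- idx %||% seq_len(dim(covs_list[[1L]])[3L])
  L <- length(model$contrasts)
  margins <- matrix(0, length(idx), L)
  for (l in seq_len(L)) {
    pc <- model$per_contrast[[l]]
    feats <- NULL
    for (b in seq_along(covs_list)) {
      cm <- pc$csp[[b]]
      fb <- cov_log_features(covs_list[[b]],
                             cm$W[, cm$selected, drop = FALSE], idx)
      feats <- if (is.null(feats)) fb else cbind(feats, fb)
    }
    margins[, l] <- fld_margin(pc$fld, feats)
  }
  margins
}

ecoc_predict_cov <- function(covs_list, model, idx = NULL) {
  as.integer(ecoc_decide(ecoc_margins_cov(covs_list, model, idx), model$M))
}
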