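#' Tidy an evaluation result into per-fold scores
#'
#' @param x An `evaluation_result`.
#' @param ... Unused.
#' @return Tibble with columns `rep`, `fold`, `dp`, `rho_t`.
#' @method tidy evaluation_result
#' @export
tidy.evaluation_result <- function(x, ...) {
  x$fold_scores
}

#' One-row summary of an evaluation result
#'
#' @param x An `evaluation_result`.
#' @param ... Unused.
#' @return Tibble: `dp`, `rho_t`, their SDs over folds, fold sizes, seed.
#' @method glance evaluation_result
#' @export
glance.evaluation_result <- function(x, ...) {
  tibble::tibble(
    dp = x$dp, rho_t = x$rho_t,
    dp_sd = sd(x$fold_scores$dp), rho_t_sd = sd(x$fold_scores$rho_t),
    n_scores = nrow(x$fold_scores), n_train = x$n_train, n_test = x$n_test,
    seed = x$seed
  )
}

#' Confusion matrix as a tidy table
#'
#' @param x An `evaluation_result`.
#' @param normalize Divide each row by its sum (per-class rates).
#' @return Tibble with `actual`, `predicted` (0-based indices), `n`, and
#'   `angle_actual`/`angle_predicted` in degrees.
#' @export
tidy_confusion <- function(x, normalize = FALSE) {
  cm <- x$confusion
  K <- nrow(cm)
  out <- tidyr::expand_grid(actual = 0:(K - 1), predicted = 0:(K - 1))
  out$n <- as.numeric(cm[cbind(out$actual + 1, out$predicted + 1)])
  if (normalize) {
    out <- dplyr::mutate(dplyr::group_by(out, .data$actual),
                         n = .data$n / sum(.data$n))
    out <- dplyr::ungroup(out)
  }
  out$angle_actual <- out$actual * 360 / K
  out$angle_predicted <- out$predicted * 360 / K
  out
}

#' Tidy the contrast table of a fitted decoder
#'
#' @param x An `ecoc_model`.
#' @param ... Unused.
#' @return Tibble with one row per contrast: `id`, `kind`, the two class
#'   sets (comma-separated, 0-based) and the per-band leading CSP
#'   eigenvalue.
#' @method tidy ecoc_model
#' @export
tidy.ecoc_model <- function(x, ...) {
  rows <- lapply(seq_along(x$contrasts), function(l) {
    ct <- x$contrasts[[l]]
    ev <- vapply(x$per_contrast[[l]]$csp,
                 function(cm) cm$eigenvalues[1L], numeric(1))
    names(ev) <- paste0("lambda1_",
                        x$band_names %||% seq_along(ev))
    dplyr::bind_cols(
      tibble::tibble(id = ct$id, kind = ct$kind,
                     positive = paste(ct$positive_set, collapse = ","),
                     negative = paste(ct$negative_set, collapse = ",")),
      tibble::as_tibble_row(ev))
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a fitted decoder
#'
#' @param x An `ecoc_model`.
#' @param ... Unused.
#' @return Tibble: class count, contrast counts, bands, features per
#'   contrast.
#' @method glance ecoc_model
#' @export
glance.ecoc_model <- function(x, ...) {
  kinds <- vapply(x$contrasts, function(ct) ct$kind, character(1))
  n_bands <- length(x$per_contrast[[1L]]$csp)
  tibble::tibble(
    K = x$K, L = length(x$contrasts),
    n_pair = sum(kinds == "pair"), n_group = sum(kinds == "group"),
    n_bands = n_bands, m = x$m, n_features = 2L * x$m * n_bands
  )
}

#' Confusion-matrix heat map
#'
#' @param object An `evaluation_result`.
#' @param normalize Plot per-class rates instead of counts.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot evaluation_result
#' @export
autoplot.evaluation_result <- function(object, normalize = TRUE, ...) {
  df <- tidy_confusion(object, normalize = normalize)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$angle_predicted),
                                   y = factor(.data$angle_actual),
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (normalize) "rate" else "count") +
    ggplot2::labs(x = "predicted direction (deg)",
                  y = "actual direction (deg)",
                  title = sprintf("DP = %.2f, rho_T = %.2f",
                                  object$dp, object$rho_t)) +
    ggplot2::theme_minimal()
}

#' Decoding-accuracy time course
#'
#' @param object A `window_sweep`.
#' @param ... Unused.
#' @return A ggplot of rho_T against window end, with the corrected-t 95%
#'   band.
#' @method autoplot window_sweep
#' @export
autoplot.window_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_end, y = .data$rho_t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "window end (ms from alignment)",
                  y = "circular correlation") +
    ggplot2::theme_minimal()
}

#' Channel- and trial-subset accuracy curves
#'
#' @param data Output of [subset_curves()].
#' @return A ggplot of mean rho_T against subset size, one facet per curve.
#' @export
plot_subset_curves <- function(data) {
  summ <- dplyr::summarise(
    dplyr::group_by(data, .data$curve, .data$count),
    rho_t = mean(.data$rho_t), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$count, y = .data$rho_t)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~curve, scales = "free_x") +
    ggplot2::labs(x = "subset size", y = "mean circular correlation") +
    ggplot2::theme_minimal()
}
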