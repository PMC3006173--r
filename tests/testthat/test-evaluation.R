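test_that("decoding power is the fraction of correct trials", {
  expect_equal(decoding_power(0:7, 0:7), 1)
  expect_equal(decoding_power(rep(1, 8), rep(2, 8)), 0)
  expect_equal(decoding_power(c(0, 1, 2, 3, 3, 3, 3, 3),
                              c(0, 1, 2, 0, 0, 0, 0, 0)), 0.375)
  expect_error(decoding_power(integer(0), integer(0)), "non-empty")
})

test_that("circular correlation hits its limit cases", {
  a <- direction_angle(rep(0:7, 4))
  expect_equal(as.numeric(circular_correlation(a, a)), 1)
  expect_equal(as.numeric(circular_correlation(-a, a)), -1)
  # invariant to adding a common rotation to both sequences
  set.seed(41)
  b <- runif(40, 0, 2 * pi)
  c2 <- runif(40, 0, 2 * pi)
  expect_equal(as.numeric(circular_correlation(b + 1.1, c2 + 1.1)),
               as.numeric(circular_correlation(b, c2)), tolerance = 1e-12)
  # degenerate constant sequence: flagged zero, not an error
  z <- circular_correlation(rep(1, 10), runif(10))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  expect_error(circular_correlation(1:2, 1:2), "length >= 3")
})

test_that("independent angle sequences decorrelate", {
  for (s in 1:3) {
    set.seed(100 + s)
    r <- circular_correlation(runif(1000, 0, 2 * pi), runif(1000, 0, 2 * pi))
    expect_lt(abs(as.numeric(r)), 0.1)
  }
})

test_that("vectorized circular correlation matches the pairwise oracle", {
  set.seed(42)
  a <- runif(25, 0, 2 * pi); b <- a + rnorm(25, sd = 0.5)
  expect_equal(as.numeric(circular_correlation(a, b)), circ_corr_loop(a, b),
               tolerance = 1e-12)
})

test_that("corrected t-test widens the naive interval by the overlap factor", {
  set.seed(43)
  J <- 100; n_train <- 288; n_test <- 32
  scores <- rnorm(J, 0.8, 0.05)
  res <- corrected_ttest(scores, 0.7, n_train, n_test)
  naive_se <- sd(scores) / sqrt(J)
  corrected_se <- (mean(scores) - 0.7) / res$statistic
  expect_equal(corrected_se / naive_se, sqrt(1 + J * n_test / n_train),
               tolerance = 1e-10)
  expect_equal(res$df, J - 1)
  # identical scores: t = 0, p = 1
  same <- corrected_ttest(scores, scores, n_train, n_test)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # constant nonzero difference: infinite t, p = 0
  const <- corrected_ttest(rep(0.9, 10), 0.8, n_train, n_test)
  expect_identical(const$statistic, Inf)
  expect_equal(const$p_value, 0)
  expect_error(corrected_ttest(0.5, 0, 10, 10), "at least 2")
})

test_that("cross-validation is deterministic, stratified and consistent", {
  cfg <- small_strong_cfg(seed = 44)
  ts <- simulate_session(cfg)
  banded <- preprocess_bands(ts, default_bands("delta"))
  res <- cross_validate(banded, window_ms = c(0, 1000), folds = 5, reps = 2,
                        seed = 9)
  res2 <- cross_validate(banded, window_ms = c(0, 1000), folds = 5, reps = 2,
                         seed = 9)
  expect_identical(res$fold_scores, res2$fold_scores)
  expect_identical(res$confusion, res2$confusion)
  # dp recomputable from the confusion matrix exactly
  expect_equal(res$dp, sum(diag(res$confusion)) / sum(res$confusion))
  # every trial tested once per repetition
  expect_equal(unname(rowSums(res$confusion)), rep(2 * 10, 8))
  expect_identical(nrow(res$fold_scores), 10L)
  # planted structure decodes well above chance
  expect_gt(res$dp, 0.7)
  # glance/tidy accessors
  expect_identical(nrow(glance(res)), 1L)
  expect_identical(tidy(res), res$fold_scores)
  # too many folds for the class size
  expect_error(cross_validate(banded, folds = 11, reps = 1, seed = 1),
               "stratification")
})

test_that("cross-session transfer degrades under parameter drift", {
  base <- sim_config(n_trials_per_class = 10L, n_channels = 10L,
                     drift = 0.6, seed = 45)
  s1 <- simulate_session(drift_session(base, 1))
  s2 <- simulate_session(drift_session(base, 2))
  bands <- default_bands("delta")
  stable <- cross_session_validate(s1, s1, bands = bands,
                                   window_ms = c(0, 1000))
  drifted <- cross_session_validate(s1, s2, bands = bands,
                                    window_ms = c(0, 1000))
  expect_gt(stable$dp, drifted$dp)
  expect_true(drifted$dp >= 0 && drifted$dp <= 1)
  # channel mismatch is refused
  s3 <- subset_trials(s2, channels = 1:5)
  expect_error(cross_session_validate(s1, s3, bands = bands), "channel")
})

test_that("subset curves: full channel count reproduces the full evaluation", {
  cfg <- small_strong_cfg(seed = 46)
  ts <- simulate_session(cfg)
  bands <- default_bands("delta")
  full <- cross_validate(preprocess_bands(ts, bands),
                         window_ms = c(0, 1000), folds = 5, reps = 1,
                         seed = 7, csp_shrinkage = 0.05)
  curves <- subset_curves(ts, channel_counts = c(4, 10), draws = 2,
                          seed = 7, bands = bands, window_ms = c(0, 1000),
                          folds = 5, reps = 1)
  full_rows <- dplyr::filter(curves, .data$count == 10)
  expect_equal(full_rows$rho_t[1], full_rows$rho_t[2])  # no resampling at C
  expect_equal(full_rows$rho_t[1], full$rho_t)          # subset identity
  # fewer channels decode worse on average
  m <- dplyr::summarise(dplyr::group_by(curves, .data$count),
                        rho = mean(.data$rho_t))
  expect_lt(m$rho[m$count == 4], m$rho[m$count == 10] + 0.05)
  expect_error(subset_curves(ts, channel_counts = 99, bands = bands),
               "exceeds")
  expect_error(subset_curves(ts, trial_counts = 99, bands = bands),
               "exceeds")
})
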