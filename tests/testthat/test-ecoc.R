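test_that("contrast enumeration matches the 28 + 12 scheme for K = 8", {
  cts <- enumerate_contrasts(8)
  kinds <- vapply(cts, function(ct) ct$kind, character(1))
  expect_length(cts, 40)
  expect_identical(sum(kinds == "pair"), 28L)
  expect_identical(sum(kinds == "group"), 12L)
  # group sides are contiguous and diametrically opposite
  for (ct in cts[kinds == "group"]) {
    expect_setequal((ct$positive_set + 4) %% 8, ct$negative_set)
    expect_true(length(ct$positive_set) %in% 2:4)
  }
  # ids are sequential and deterministic
  expect_identical(vapply(cts, function(ct) ct$id, integer(1)), 1:40)
  expect_identical(enumerate_contrasts(8), cts)
})

test_that("contrast enumeration handles K = 4 and rejects odd K", {
  cts <- enumerate_contrasts(4)
  kinds <- vapply(cts, function(ct) ct$kind, character(1))
  expect_length(cts, 8)              # 6 pairs + 2 deduplicated groups
  expect_identical(sum(kinds == "pair"), 6L)
  expect_identical(sum(kinds == "group"), 2L)
  expect_error(enumerate_contrasts(7), "even")
  expect_error(enumerate_contrasts(2), ">= 4")
})

test_that("the code matrix encodes contrasts with entries in {-1, 0, 1}", {
  cts <- enumerate_contrasts(8)
  M <- build_code_matrix(cts, 8)
  expect_identical(dim(M), c(8L, 40L))
  expect_true(all(M %in% c(-1L, 0L, 1L)))
  # pair columns: one +1, one -1, six 0
  pair_cols <- which(vapply(cts, function(ct) ct$kind, "") == "pair")
  for (l in pair_cols) {
    expect_identical(sum(M[, l] == 1), 1L)
    expect_identical(sum(M[, l] == -1), 1L)
  }
  # each class is active in exactly K - 1 = 7 pair columns
  expect_identical(unname(rowSums(M[, pair_cols] != 0)), rep(7, 8))
  # every column balances its sides
  expect_identical(unname(colSums(M)), rep(0, 40))
  # dropping group contrasts leaves the pairwise sub-matrix untouched
  M_pairs <- build_code_matrix(cts[pair_cols], 8)
  expect_identical(M_pairs, M[, pair_cols])
})

test_that("oracle margins decode every class; ties go to class 0", {
  cts <- enumerate_contrasts(8)
  M <- build_code_matrix(cts, 8)
  for (k in 0:7) {
    expect_identical(as.integer(ecoc_decide(oracle_margins(k, cts), M)), k)
  }
  expect_identical(as.integer(ecoc_decide(numeric(40), M)), 0L)
})

test_that("the fused decision equals the exhaustive minimum score", {
  cts <- enumerate_contrasts(8)
  M <- build_code_matrix(cts, 8)
  set.seed(21)
  for (i in 1:25) {
    y <- rnorm(40)
    scores <- vapply(1:8, function(k) -sum(M[k, ] * y), numeric(1))
    expect_identical(as.integer(ecoc_decide(y, M)),
                     as.integer(which.min(scores) - 1L))
  }
})

test_that("the Fisher discriminant recovers the closed-form direction", {
  set.seed(22)
  # 1-D symmetric case: threshold at 0
  f1 <- matrix(c(rnorm(300, 1), rnorm(300, -1)), ncol = 1)
  y1 <- rep(c(1, -1), each = 300)
  m1 <- fld_fit(f1, y1, shrinkage = 0)
  expect_equal(m1$b / m1$w, 0, tolerance = 0.15)
  expect_gt(fld_margin(m1, 1), 0)
  expect_lt(fld_margin(m1, -1), 0)
  # identical means: no signal, training accuracy ~ 1/2
  f0 <- matrix(rnorm(400 * 2), ncol = 2)
  y0 <- rep(c(1, -1), 200)
  m0 <- fld_fit(f0, y0, shrinkage = 0)
  expect_lt(abs(mean(sign(fld_margin(m0, f0)) == y0) - 0.5), 0.1)
  # 2-D anisotropic Gaussians: w parallel to solve(S, dmu) within 5 degrees
  S <- matrix(c(2, 1.2, 1.2, 1.5), 2)
  L <- chol(S)
  mu <- c(1, 0.5)
  X <- rbind(matrix(rnorm(2000 * 2), ncol = 2) %*% L + rep(mu, each = 2000),
             matrix(rnorm(2000 * 2), ncol = 2) %*% L - rep(mu, each = 2000))
  y <- rep(c(1, -1), each = 2000)
  m2 <- fld_fit(X, y, shrinkage = 0)
  w_true <- solve(S, 2 * mu)
  ang <- acos(sum(m2$w * w_true) / sqrt(sum(m2$w^2) * sum(w_true^2)))
  expect_lt(ang * 180 / pi, 5)
  # midpoint margin is 0 by construction
  expect_equal(fld_margin(m2, (colMeans(X[y > 0, ]) + colMeans(X[y < 0, ])) / 2),
               0, tolerance = 1e-10)
  expect_error(fld_fit(f1, rep(1, 600)), "single-class")
  expect_error(fld_margin(m2, c(1, 2, 3)), "mismatch")
})

test_that("the fitted decoder concatenates six features per band", {
  cfg <- small_strong_cfg(seed = 31)
  ts <- simulate_session(cfg)
  banded <- preprocess_bands(ts, default_bands(c("delta", "gamma")))
  model <- ecoc_fit(banded, window_ms = c(0, 1000))
  g <- glance(model)
  expect_identical(g$L, 40L)
  expect_identical(g$n_features, 12L)     # 2 bands x 2m = 12
  expect_length(model$per_contrast[[1]]$fld$w, 12L)
  expect_identical(nrow(tidy(model)), 40L)
  # training-set decoding power is high for the planted structure
  window <- window_samples(banded[[1]], c(0, 1000))
  covs <- lapply(banded, trial_covariances, window = window)
  pred <- lfpdecoder:::ecoc_predict_cov(covs, model)
  expect_gt(decoding_power(pred, ts$labels), 0.9)
  # determinism: identical refit
  model2 <- ecoc_fit(banded, window_ms = c(0, 1000))
  expect_equal(model, model2)
})

test_that("training fails loudly when a class has fewer than 2 trials", {
  cfg <- small_strong_cfg(seed = 32)
  ts <- simulate_session(cfg)
  keep <- c(which(ts$labels == 3)[1], which(ts$labels != 3))
  sub <- subset_trials(ts, trials = keep)
  banded <- preprocess_bands(sub, default_bands("delta"))
  expect_error(ecoc_fit(banded, window_ms = c(0, 1000)), "class 3")
})

test_that("single-trial prediction agrees with the batch covariance path", {
  cfg <- small_strong_cfg(seed = 33)
  ts <- simulate_session(cfg)
  banded <- preprocess_bands(ts, default_bands(c("delta", "gamma")))
  model <- ecoc_fit(banded, window_ms = c(0, 1000))
  window <- window_samples(banded[[1]], c(0, 1000))
  covs <- lapply(banded, trial_covariances, window = window)
  batch <- lfpdecoder:::ecoc_predict_cov(covs, model, idx = 1:5)
  single <- vapply(1:5, function(tr) {
    ecoc_predict(lapply(banded, function(tb) tb$data[tr, , window]), model)
  }, integer(1))
  expect_identical(single, batch)
})

test_that("rotating all labels rotates the predictions", {
  cfg <- small_strong_cfg(seed = 34)
  ts <- simulate_session(cfg)
  banded <- preprocess_bands(ts, default_bands("delta"))
  window <- window_samples(banded[[1]], c(0, 1000))
  covs <- lapply(banded, trial_covariances, window = window)
  m1 <- ecoc_fit(banded, window_ms = c(0, 1000))
  p1 <- lfpdecoder:::ecoc_predict_cov(covs, m1)
  rot <- lapply(banded, function(tb) {
    tb$labels <- (tb$labels + 1L) %% 8L
    tb
  })
  m2 <- ecoc_fit(rot, window_ms = c(0, 1000))
  p2 <- lfpdecoder:::ecoc_predict_cov(covs, m2)
  expect_identical(p2, (p1 + 1L) %% 8L)
})
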