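test_that("trial mean removal zeroes each channel mean and is idempotent", {
  ts <- noise_trialset(n_trials = 3, n_channels = 2, n_samples = 100)
  ts$data[1, 1, ] <- 5
  ts$data[2, 2, ] <- 1:100 * 0 + c(1, 2, 3, rep(2, 97))
  out <- remove_trial_mean(ts)
  means <- apply(out$data, c(1, 2), mean)
  expect_true(all(abs(means) < 1e-12))
  expect_equal(out$data[1, 1, ], rep(0, 100))
  expect_equal(remove_trial_mean(out)$data, out$data)
  # [1,2,3] -> [-1,0,1]
  ts2 <- trial_set(array(c(1, 2, 3), c(1, 1, 3)), fs = 1000, labels = 0L)
  expect_equal(as.numeric(remove_trial_mean(ts2)$data), c(-1, 0, 1))
})

test_that("band-pass design hits -6 dB at the cutoffs and unity mid-band", {
  for (spec in list(subband_spec(48, 200), subband_spec(14, 22),
                    subband_spec(22, 30))) {
    h <- design_bandpass(spec, 500)
    expect_equal(fir_gain(h, spec$low, 500), 0.5, tolerance = 0.05)
    expect_equal(fir_gain(h, spec$high, 500), 0.5, tolerance = 0.05)
    expect_equal(fir_gain(h, (spec$low + spec$high) / 2, 500), 1,
                 tolerance = 0.05)
  }
  # coefficients are symmetric (linear phase)
  h <- design_bandpass(subband_spec(4, 10), 500)
  expect_equal(as.numeric(h), rev(as.numeric(h)))
  # the delta band is designed as a low-pass with -6 dB at the high edge
  hd <- design_bandpass(subband_spec(0.3, 4, FALSE), 500)
  expect_identical(attr(hd, "type"), "low")
  expect_equal(fir_gain(hd, 4, 500), 0.5, tolerance = 0.05)
  # an explicit order below the transition-width rule is refused
  expect_error(design_bandpass(subband_spec(48, 200, filter_order = 50), 500),
               "configuration error")
  expect_error(subband_spec(10, 4), "configuration error")
})

test_that("forward filtering with N/2 shift is zero-phase", {
  h <- design_bandpass(subband_spec(4, 10), 500)
  N <- attr(h, "order")
  # impulse at sample k comes out as h centered at k
  x <- numeric(2000); k <- 900; x[k] <- 1
  y <- filter_zero_phase(x, h)
  expect_equal(which.max(abs(y)), k)
  expect_equal(y[k + (-50:50)], as.numeric(h)[N / 2 + 1 + (-50:50)])
  # in-band tone keeps its phase: peak cross-correlation at lag 0
  tone <- sin(2 * pi * 7 * (0:1999) / 500)
  yt <- filter_zero_phase(tone, h)
  ccf <- sapply(-5:5, function(l) {
    idx <- 700:1300
    cor(tone[idx], yt[idx + l])
  })
  expect_equal(which.max(ccf), 6L)  # lag 0
  expect_equal(filter_zero_phase(numeric(1000), h), numeric(1000))
  expect_error(filter_zero_phase(numeric(100), h), "shorter")
})

test_that("the analytic-signal envelope recovers amplitude and modulator", {
  fs <- 500
  t <- (0:1999) / fs
  x <- 2 * sin(2 * pi * 80 * t)
  e <- hilbert_envelope(x)
  inner <- 101:1900
  expect_equal(mean(e[inner]), 2, tolerance = 0.01)
  # flat to < 2% coefficient of variation away from edges
  expect_lt(sd(e[inner]) / mean(e[inner]), 0.02)
  # AM carrier: envelope tracks the modulator
  mod <- 1 + 0.5 * cos(2 * pi * 2 * t)
  am <- mod * sin(2 * pi * 80 * t)
  expect_equal(hilbert_envelope(am)[inner], mod[inner], tolerance = 0.02)
  expect_equal(hilbert_envelope(numeric(64)), numeric(64))
})

test_that("sub-band preprocessing decimates, signs and gates as specified", {
  ts <- noise_trialset(n_trials = 2, n_channels = 3, n_samples = 3000,
                       fs = 1000)
  delta <- preprocess_subband(ts, default_bands()$delta)
  expect_identical(dim(delta$data)[3], 300L)   # ceil(3000 * 100/1000)
  expect_equal(delta$fs_out, 100)
  expect_true(any(delta$data < 0))             # signed amplitude band
  gamma <- preprocess_subband(ts, default_bands()$gamma)
  expect_true(all(gamma$data >= 0))            # envelope band
  # masked channels are dropped, with original indices kept
  ts$channel_mask <- c(TRUE, FALSE, TRUE)
  kept <- preprocess_subband(ts, default_bands()$gamma)
  expect_identical(kept$channels, c(1L, 3L))
  expect_identical(dim(kept$data)[2], 2L)
})

test_that("preprocessing is per-trial: it commutes with trial reordering", {
  ts <- noise_trialset(n_trials = 4, n_channels = 2, n_samples = 2000,
                       fs = 1000)
  ord <- c(3, 1, 4, 2)
  a <- preprocess_subband(ts, default_bands()$gamma)
  b <- preprocess_subband(subset_trials(ts, trials = ord),
                          default_bands()$gamma)
  expect_equal(b$data, a$data[ord, , , drop = FALSE])
})

test_that("decimation after the 30 Hz low-pass does not alias a 45 Hz tone", {
  fs <- 1000
  t <- (0:5999) / fs
  carrier <- sin(2 * pi * 100 * t) * (1 + 0.8 * sin(2 * pi * 45 * t))
  ts <- trial_set(array(rep(carrier, 2), c(1, 2, 6000)), fs = fs,
                  labels = 0L)
  out <- preprocess_subband(ts, subband_spec(80, 120))
  sig <- out$data[1, 1, 50:550]
  spec <- Mod(fft(sig - mean(sig)))^2
  freqs <- (seq_along(spec) - 1) * 100 / length(spec)
  p45 <- max(spec[abs(freqs - 45) < 1.5])
  p_pass <- max(spec[freqs > 0.5 & freqs < 25])
  expect_gt(10 * log10(p_pass / p45), 20)
})

test_that("time-frequency maps are percent change against baseline", {
  set.seed(3)
  fs <- 500
  n <- 3000
  # white noise whose 20 Hz component doubles in amplitude after t = 0
  t0 <- -3000
  dat <- array(rnorm(8 * 1 * n, sd = 1), c(8, 1, n))
  ts <- trial_set(dat, fs = fs, labels = rep_len(0:7, 8), t0_ms = t0)
  m0 <- time_frequency_map(ts, baseline_window_ms = c(-3000, 0), channel = 1)
  expect_lt(abs(mean(m0)), 15)   # stationary noise: ~0% everywhere
  tone <- sin(2 * pi * 20 * (0:(n - 1)) / fs) * 3
  tone[1:(n / 2)] <- 0           # only after t = 0 (t0 = -3000 ms)
  ts$data[, 1, ] <- sweep(ts$data[, 1, ], 2, -tone)
  m1 <- time_frequency_map(ts, baseline_window_ms = c(-2800, -200),
                           channel = 1)
  f20 <- which.min(abs(attr(m1, "freq_hz") - 20))
  late <- attr(m1, "time_ms") > 300
  early <- attr(m1, "time_ms") < -300
  expect_gt(mean(m1[f20, late]), 100)       # large power increase at 20 Hz
  expect_lt(abs(mean(m1[f20, early])), 50)  # none before onset
})
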