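# Small in-code fixtures shared across test files.

# white-noise trial set
noise_trialset <- function(n_trials = 4, n_channels = 3, n_samples = 1000,
                           fs = 1000, seed = 1, K = 8L) {
  set.seed(seed)
  trial_set(
    data = array(rnorm(n_trials * n_channels * n_samples),
                 dim = c(n_trials, n_channels, n_samples)),
    fs = fs,
    labels = rep_len(0:(K - 1), n_trials),
    t0_ms = 0, K = K
  )
}

# desk-scale strong-effect session: smaller than the default geometry but
# with the same planted structure
small_strong_cfg <- function(seed = 11, ...) {
  sim_config(n_trials_per_class = 10L, n_channels = 10L, seed = seed, ...)
}

# frequency response magnitude of an FIR filter
fir_gain <- function(h, f, fs) {
  k <- seq_along(h) - 1
  abs(sum(h * exp(-2i * pi * f * k / fs)))
}

# independent double-loop implementation of the Fisher-Lee T-linear
# association, used as the oracle for the vectorized version
circ_corr_loop <- function(a, b) {
  n <- length(a)
  num <- d1 <- d2 <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      num <- num + sin(a[i] - a[j]) * sin(b[i] - b[j])
      d1 <- d1 + sin(a[i] - a[j])^2
      d2 <- d2 + sin(b[i] - b[j])^2
    }
  }
  num / sqrt(d1 * d2)
}

# margins an ideal bank of binary classifiers would emit for a true class
oracle_margins <- function(true_class, contrasts) {
  vapply(contrasts, function(ct) {
    if (true_class %in% ct$positive_set) 1
    else if (true_class %in% ct$negative_set) -1
    else 0
  }, numeric(1))
}
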