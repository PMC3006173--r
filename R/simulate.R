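#' Configuration of the synthetic direction-tuned session generator
#'
#' The generator plants the two statistical structures the decoder
#' exploits: a slow (0.3–4 Hz) component whose inter-channel covariance
#' varies smoothly and 360-degree-periodically with target direction (a von
#' Mises mixture of a few "columnar" source patterns), and a fast
#' (48–200 Hz) carrier whose envelope gain is cosine-tuned per channel.
#' Both effects follow the task timeline: absent during the pre-cue
#' baseline, present at a fraction `delay_leak` from cue onset through the
#' instructed delay, ramping to full strength at movement onset. Spatially
#' correlated pink noise and optional mains contamination complete the
#' signal.
#'
#' Epoch defaults follow the instructed-delay center-out task: 800 ms
#' baseline hold, 600 ms cue, 900 ms delay, 1000 ms movement, aligned to
#' movement onset.
#'
#' @param n_trials_per_class Trials per direction (default 40).
#' @param n_channels Channels (default 32, past the knee of the
#'   channel-count curve).
#' @param K Directions (default 8).
#' @param fs Sampling rate, Hz (default 1000).
#' @param epoch Named list `baseline_ms`, `cue_ms`, `delay_ms`, `move_ms`.
#' @param delta_sources Number of slow source patterns (default 6).
#' @param kappa Von Mises concentration of the source tuning (default 2).
#' @param delta_effect Depth of direction-dependent mixing, `[0, 1]`.
#' @param gamma_depth Depth of envelope-gain tuning, `[0, 1]`.
#' @param delay_leak Fraction of the full effect present during the delay,
#'   `[0, 1]`.
#' @param noise_sigma SD of the pink background noise.
#' @param common_noise_frac Fraction of noise variance shared across
#'   channels, `[0, 1]`.
#' @param drift SD of cross-session parameter jitter (see
#'   [drift_session()]).
#' @param line_noise_channels Channel indices receiving a 60 Hz sinusoid.
#' @param line_noise_amp Amplitude of that sinusoid.
#' @param delta_amp,gamma_amp Component amplitudes (slow signal SD and mean
#'   carrier SD).
#' @param ramp_ms Rise time of the effect before movement onset.
#' @param seed Mandatory integer seed; every draw derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_trials_per_class = 40L, n_channels = 32L, K = 8L,
                       fs = 1000,
                       epoch = list(baseline_ms = 800, cue_ms = 600,
                                    delay_ms = 900, move_ms = 1000),
                       delta_sources = 6L, kappa = 2, delta_effect = 0.8,
                       gamma_depth = 0.5, delay_leak = 0,
                       noise_sigma = 0.5, common_noise_frac = 0.3,
                       drift = 0, line_noise_channels = integer(0),
                       line_noise_amp = 5, delta_amp = 1, gamma_amp = 0.5,
                       ramp_ms = 300, seed) {
  if (missing(seed)) stop("invalid config: seed is mandatory", call. = FALSE)
  for (p in c(delta_effect, gamma_depth, delay_leak, common_noise_frac)) {
    if (p < 0 || p > 1) {
      stop("invalid config: depths and fractions must lie in [0, 1]",
           call. = FALSE)
    }
  }
  if (any(unlist(epoch) <= 0)) {
    stop("invalid config: epoch durations must be positive", call. = FALSE)
  }
  structure(
    list(n_trials_per_class = as.integer(n_trials_per_class),
         n_channels = as.integer(n_channels), K = as.integer(K), fs = fs,
         epoch = epoch, delta_sources = as.integer(delta_sources),
         kappa = kappa, delta_effect = delta_effect,
         gamma_depth = gamma_depth, delay_leak = delay_leak,
         noise_sigma = noise_sigma, common_noise_frac = common_noise_frac,
         drift = drift, line_noise_channels = as.integer(line_noise_channels),
         line_noise_amp = line_noise_amp, delta_amp = delta_amp,
         gamma_amp = gamma_amp, ramp_ms = ramp_ms, seed = as.integer(seed),
         phase_jitter = NULL, gain_jitter = NULL, session_id = 1L),
    class = "sim_config"
  )
}

# task-epoch gating of the planted effect: 0 before the cue, delay_leak
# from cue onset, linear rise to 1 over the last ramp_ms before movement
# onset, 1 afterwards
epoch_ramp <- function(t_ms, cfg) {
  cue_start <- -(cfg$epoch$cue_ms + cfg$epoch$delay_ms)
  r <- numeric(length(t_ms))
  r[t_ms >= cue_start] <- cfg$delay_leak
  rise <- t_ms >= -cfg$ramp_ms & t_ms < 0
  r[rise] <- cfg$delay_leak +
    (1 - cfg$delay_leak) * (t_ms[rise] + cfg$ramp_ms) / cfg$ramp_ms
  r[t_ms >= 0] <- 1
  r
}

# normalized per-source direction gains: von Mises bumps rescaled so the
# summed squared gain (total slow power) is direction-independent
source_gains <- function(theta, phases, kappa) {
  v <- exp(kappa * cos(theta - phases))
  v * sqrt(length(phases) / sum(v^2))
}

# unit-SD pink (1/f amplitude) noise columns
pink_noise <- function(n, ncols) {
  nf <- n %/% 2
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  out <- matrix(0, n, ncols)
  for (j in seq_len(ncols)) {
    spec <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * amp
    full <- complex(length.out = n)
    full[2:(nf + 1)] <- spec
    full[seq(n, n - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
    x <- Re(fft(full, inverse = TRUE)) / n
    out[, j] <- x / sd(x)
  }
  out
}

# session-level latent parameters, derived deterministically from the seed
session_params <- function(cfg) {
  C <- cfg$n_channels; S <- cfg$delta_sources
  with_seed(cfg$seed, {
    P <- matrix(rnorm(C * S), C, S) / sqrt(C)       # source spatial patterns
    src_phase <- 2 * pi * (seq_len(S) - 1) / S
    gamma_pref <- runif(C, 0, 2 * pi)               # per-channel gamma tuning
    b <- runif(C, 0.8, 1.2) * cfg$gamma_amp         # baseline envelope gain
    line_phase <- runif(C, 0, 2 * pi)
    list(P = P, src_phase = src_phase, gamma_pref = gamma_pref, b = b,
         line_phase = line_phase)
  })
}

apply_drift <- function(par, cfg) {
  if (!is.null(cfg$phase_jitter)) {
    par$src_phase <- par$src_phase + cfg$phase_jitter
  }
  if (!is.null(cfg$gain_jitter)) {
    par$b <- pmax(par$b + cfg$gain_jitter, 0.05 * cfg$gamma_amp)
  }
  par
}

#' Simulate one direction-tuned LFP session
#'
#' Generates a full trial-epoched session with the structure described in
#' [sim_config()]. Reproducible bit-for-bit from the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A `trial_set`; attribute `"ground_truth"` records the latent
#'   session parameters (source phases, gamma preferences and gains, trial
#'   angles) and the resolved config.
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  C <- cfg$n_channels; S <- cfg$delta_sources; K <- cfg$K
  n <- round(sum(unlist(cfg$epoch)) * cfg$fs / 1000)
  t0 <- -(cfg$epoch$baseline_ms + cfg$epoch$cue_ms + cfg$epoch$delay_ms)
  t_ms <- t0 + (seq_len(n) - 1) * 1000 / cfg$fs
  r <- epoch_ramp(t_ms, cfg)
  par <- apply_drift(session_params(cfg), cfg)

  h_delta <- design_bandpass(subband_spec(0.3, 4, FALSE, name = "delta"),
                             cfg$fs)
  h_gamma <- design_bandpass(subband_spec(48, 200, name = "gamma"), cfg$fs)

  n_trials <- cfg$n_trials_per_class * K
  data <- array(0, dim = c(n_trials, C, n))
  labels <- with_seed(cfg$seed + 1L,
                      sample(rep(0:(K - 1L), cfg$n_trials_per_class)))
  with_seed(cfg$seed + 2L, {
    for (tr in seq_len(n_trials)) {
      theta <- direction_angle(labels[tr], K)
      # slow component: direction-tuned mixing of band-limited sources
      src <- fft_filter_mat(matrix(rnorm(n * S), n, S), h_delta)
      src <- sweep(src, 2L, apply(src, 2L, sd), "/")
      u <- source_gains(theta, par$src_phase, cfg$kappa)
      er <- cfg$delta_effect * r
      gains <- outer(1 - er, rep(1, S)) + outer(er, u)
      delta_cmp <- cfg$delta_amp * ((src * gains) %*% t(par$P))
      # fast component: cosine-tuned envelope gain on independent carriers
      carrier <- fft_filter_mat(matrix(rnorm(n * C), n, C), h_gamma)
      carrier <- sweep(carrier, 2L, apply(carrier, 2L, sd), "/")
      tune <- cfg$gamma_depth * cos(theta - par$gamma_pref)
      gain <- sweep(1 + outer(r, tune), 2L, par$b, "*")
      gamma_cmp <- carrier * gain
      # spatially correlated pink background
      p0 <- pink_noise(n, 1L)
      pc <- pink_noise(n, C)
      noise <- cfg$noise_sigma *
        (sqrt(cfg$common_noise_frac) * matrix(p0, n, C) +
           sqrt(1 - cfg$common_noise_frac) * pc)
      trial <- delta_cmp + gamma_cmp + noise
      if (length(cfg$line_noise_channels)) {
        for (ch in cfg$line_noise_channels) {
          trial[, ch] <- trial[, ch] + cfg$line_noise_amp *
            sin(2 * pi * 60 * t_ms / 1000 + par$line_phase[ch])
        }
      }
      data[tr, , ] <- t(trial)
    }
  })
  out <- trial_set(data = data, fs = cfg$fs, labels = labels,
                   alignment = "movement_onset", t0_ms = t0,
                   session_id = cfg$session_id, K = K)
  attr(out, "ground_truth") <- list(
    config = cfg, src_phase = par$src_phase, gamma_pref = par$gamma_pref,
    gamma_gain = par$b, angles_deg = labels * 360 / K)
  out
}

#' Analytic slow-component covariance of a direction
#'
#' The mixing model implies a peri-movement (ramp = 1) slow-component
#' covariance with the closed form `delta_amp^2 * P diag(g(theta)^2) P'`;
#' this helper evaluates it for inspecting how the planted covariance moves
#' with direction.
#'
#' @param cfg A [sim_config()].
#' @param theta Direction angle, radians.
#' @return `C x C` covariance matrix.
#' @export
analytic_delta_covariance <- function(cfg, theta) {
  par <- apply_drift(session_params(cfg), cfg)
  u <- source_gains(theta, par$src_phase, cfg$kappa)
  g <- (1 - cfg$delta_effect) + cfg$delta_effect * u
  cfg$delta_amp^2 * par$P %*% (g^2 * t(par$P))
}

#' Simulate cosine-tuned Poisson spike trains
#'
#' Each unit fires as an inhomogeneous Poisson process with rate
#' `base_rate * (1 + mod_depth * cos(theta - theta_pref)) * ramp(t)`,
#' preferred directions uniform on the circle, the task-epoch ramp shared
#' with the LFP generator.
#'
#' @param cfg A [sim_config()] (epoch, K, trial counts, delay_leak, seed).
#' @param n_units Number of units (default 24).
#' @param base_rate Peak-epoch baseline rate, Hz (default 10).
#' @param mod_depth Cosine modulation depth, `[0, 1]`.
#' @return A `spike_set`; attribute `"ground_truth"` records the preferred
#'   directions.
#' @export
simulate_spikes <- function(cfg, n_units = 24L, base_rate = 10,
                            mod_depth = 0.5) {
  stopifnot(inherits(cfg, "sim_config"))
  if (base_rate * (1 - mod_depth) < 0) {
    stop("invalid config: rate would be negative", call. = FALSE)
  }
  K <- cfg$K
  n_ms <- round(sum(unlist(cfg$epoch)))
  t0 <- -(cfg$epoch$baseline_ms + cfg$epoch$cue_ms + cfg$epoch$delay_ms)
  t_ms <- t0 + seq_len(n_ms) - 0.5          # 1 ms bin centers
  r <- epoch_ramp(t_ms, cfg)
  n_trials <- cfg$n_trials_per_class * K
  labels <- with_seed(cfg$seed + 3L,
                      sample(rep(0:(K - 1L), cfg$n_trials_per_class)))
  units <- with_seed(cfg$seed + 4L, {
    pref <- runif(n_units, 0, 2 * pi)
    lapply(seq_len(n_units), function(u) {
      lapply(seq_len(n_trials), function(tr) {
        theta <- direction_angle(labels[tr], K)
        lam <- base_rate * (1 + mod_depth * cos(theta - pref[u])) * r / 1000
        counts <- rpois(n_ms, lam)
        idx <- rep(seq_len(n_ms), counts)
        if (!length(idx)) return(numeric(0))
        sort(t0 + idx - 1 + runif(length(idx)))
      })
    })
  })
  out <- spike_set(units, labels, alignment = "movement_onset",
                   session_id = cfg$session_id, K = K)
  attr(out, "ground_truth") <- with_seed(cfg$seed + 4L,
                                         list(pref = runif(n_units, 0, 2 * pi)))
  out
}

#' Derive a drifted session configuration
#'
#' Jitters the slow-source mixing phases and the gamma baseline gains with
#' Gaussian noise of SD `drift`, deterministically per (seed,
#' session_index), emulating the non-stationarity of chronic recordings
#' between sessions. With `drift = 0` the configuration is returned
#' unchanged (apart from `session_id`).
#'
#' @param cfg A [sim_config()].
#' @param session_index Integer session number.
#' @return A modified `sim_config`.
#' @export
drift_session <- function(cfg, session_index) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$session_id <- as.integer(session_index)
  if (cfg$drift <= 0) return(cfg)
  seed2 <- (cfg$seed + 104729L * as.integer(session_index)) %% 2147483647L
  jit <- with_seed(seed2, {
    list(phase = rnorm(cfg$delta_sources, 0, cfg$drift),
         gain = rnorm(cfg$n_channels, 0, cfg$drift * cfg$gamma_amp))
  })
  cfg$phase_jitter <- jit$phase
  cfg$gain_jitter <- jit$gain
  cfg
}
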