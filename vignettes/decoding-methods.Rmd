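---
title: "Decoding movement direction from LFP spatial patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding movement direction from LFP spatial patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpdecoder)
```

## The decoding problem

During an instructed-delay center-out reaching task, the direction of an
upcoming arm movement is reflected in multichannel local field potentials
(LFP) recorded from motor and premotor cortex — not primarily in the
amplitude of any single channel, but in the *correlation structure across
channels*, which changes smoothly and periodically with target direction.
`lfpdecoder` classifies single trials into one of K = 8 equally spaced
directions (45° apart, 0° along +x, counterclockwise) by exploiting exactly
that structure.

The pipeline has three stages:

1. **Sub-band preprocessing.** Trial tensors (trials × channels × samples,
   1 kHz) are mean-centered per trial and channel, decomposed into five
   sub-bands (0.3–4, 4–10, 14–22, 22–30 and 48–200 Hz) with linear-phase
   Blackman-window FIR filters applied forward and advanced by N/2 samples,
   reduced to the signed amplitude (0.3–4 Hz) or the Hilbert-envelope
   instantaneous amplitude (all higher bands), low-pass filtered at 30 Hz
   and decimated to 100 Hz.
2. **Common Spatial Patterns (CSP) features.** For a binary contrast of
   direction classes with class covariances $\Sigma_1, \Sigma_2$, the
   spatial filters $W$ solve the generalized eigenproblem
   $\Sigma_1 w = \lambda (\Sigma_1 + \Sigma_2) w$; the eigenvalue
   $\lambda \in [0,1]$ is the fraction of composite variance captured by
   class 1, so leading filters maximize class-1 variance and trailing
   filters minimize it. The three largest and three smallest eigenvectors
   give six log-variance features per band per contrast.
3. **ECOC fusion of a Fisher-discriminant bank.** Direction is decided by a
   redundant code: all 28 pairwise contrasts plus 12 contrasts of 2–4
   contiguous directions against their diametric opposites, L = 40 binary
   Fisher linear discriminants in total. With code matrix
   $M \in \{-1,0,1\}^{K \times L}$ and margin vector $y$, the decision is
   $\arg\min_k \left(-\sum_l m_{kl} y_l\right)$, ties to the lowest class
   index.

Everything downstream — decoding power (DP, the fraction of correctly
classified trials), the Fisher–Lee circular correlation $\rho_T$ between
predicted and actual angles, 10×10-fold stratified cross-validation with
the Nadeau–Bengio corrected t-test, sliding-window time courses,
cross-session transfer, and channel/trial subset curves — evaluates that
classifier.

## Design choices and their rationale

### Filter design

The band filters are direct Blackman windowed-sinc designs. A symmetric
windowed design has magnitude exactly 0.5 (−6 dB) at each band edge at any
order, which is the contract the pipeline relies on; frequency-sampling
designs (e.g. `signal::fir1`) place that point half a design-grid bin away
from the requested edge, which is why the package carries its own
twenty-line design routine.

The order rule is $N = \lceil 5.5 f_s / \Delta f \rceil$ (rounded up to
even), the Blackman main-lobe width heuristic, with transition width
$\Delta f = \max(0.25 \cdot f_{low}, 4\,\mathrm{Hz})$. The floor of 4 Hz is
deliberate: trial epochs are a few seconds long, and transition widths much
below ~2 Hz per side would demand filters longer than the data
(sub-hertz transitions at 500 Hz sampling need >10⁴ taps). For the 0.3–4 Hz
band the transition would cross DC, so that band is designed as a 4 Hz
low-pass: a 0.3 Hz corner is not resolvable on trial-length epochs, and in
practice it is supplied by the acquisition hardware high-pass together with
per-trial mean removal. Filters are applied by FFT convolution on
zero-padded signals; the first and last N/2 output samples are
edge-contaminated, and each `subband_tensor` records that span
(`edge_samples`) so analysts can keep analysis windows clear of it.

The fixed pipeline stages use the same rule: a 220 Hz low-pass before
decimation from 1 kHz to 500 Hz, and a 30 Hz low-pass before decimation to
100 Hz (its stopband begins at 40 Hz, below the final 50 Hz Nyquist, and a
45 Hz envelope component is attenuated by far more than 20 dB).

### Covariances and CSP

Class covariances are averages of per-trial channel covariances, each
trial normalized by its trace first so that trials contribute spatial
pattern rather than amplitude (classic CSP practice; configurable off).
When channels outnumber the smaller contrast side the average is
rank-deficient, so a shrinkage $(1-\gamma)\Sigma + \gamma
(\mathrm{tr}\,\Sigma / C) I$ with $\gamma = 0.05$ is applied automatically
(explicit `csp_shrinkage` overrides). The generalized eigenproblem is
solved by whitening the composite covariance; columns of $W$ are scaled so
$W^\top(\Sigma_1+\Sigma_2)W = I$ and sign-fixed so each filter's
largest-magnitude element is positive, making fits reproducible across
linear-algebra backends. With fewer than six channels the 3+3 selection is
clamped to $\lfloor C/2 \rfloor$ filters per end.

Features and covariances are computed on the same analysis window: the
log-variance of a projection over a window equals $w^\top S w$ with $S$ the
trial's window covariance, so per-trial covariances are the sufficient
statistics for the entire classifier. This is also what makes repeated
cross-validation cheap: the per-trial covariances are computed once and
every fold's CSP/FLD refit consumes subsets of them, with no information
flowing from test trials into training (each trial's covariance involves
that trial alone).

### Classifier bank

The Fisher discriminants use
$w = (S_w + \gamma\,(\mathrm{tr}\,S_w/d)\,I)^{-1}(\mu_+ - \mu_-)$ with
$\gamma = 0.1$ by default: the concatenated feature vector is 12-dimensional
for two bands and is estimated from tens of trials per contrast, which
needs conditioning. The bias puts the decision boundary midway between
projected class means. ECOC margins are fused raw (not binarized): soft
decoding degrades gracefully and requires no calibration. Group contrasts
pool their member classes' trials on each side; trials of classes outside a
contrast never enter its training. Ties in the class score are broken
toward the lowest class index, for determinism.

### Evaluation protocol

Cross-validation is stratified per class, with a single master seed
expanding into all fold assignments; identical seeds give bit-identical
fold scores. CSP and FLD are refit inside every training partition and for
every sliding-window position — the conservative reading of the protocol,
preventing temporal as well as trial leakage. The corrected t-test inflates
the variance of a mean of J fold scores to
$\hat\sigma^2 (1/J + n_{test}/n_{train})$ with $J-1$ degrees of freedom,
compensating for the overlap of training sets across folds.

Sliding-window protocols: cue-aligned, 500 ms windows stepped by 100 ms
with ends from 0 to +1200 ms (13 positions); movement-aligned, 1000 ms
windows with ends from −400 to +1000 ms (15 positions). Window positions
are derived from start/step/end, and however many fit are reported. The
delay-period information test sums per-fold $\rho_T$ over the window
positions ending inside the delay and tests the sum against zero with the
corrected t-test — matched fold partitions across windows (same master
seed) make the per-fold sums meaningful.

A degenerate prediction sequence (decoder stuck on one class) yields
$\rho_T = 0$ flagged with an attribute rather than an error, so sweep
series remain complete and plottable.

Channel-subset curves draw channels with replacement, as in the original
protocol; the resulting duplicated channels are exactly what the CSP
shrinkage default exists to absorb. The one exception is the full channel
count, which uses every channel once so the curve's endpoint coincides with
the full evaluation. Trial-subset curves balance trials per class to avoid
class-prior bias.

### Spike decoding

Sorted spike times are binned in 2 ms windows, giving 500 Hz-equivalent
count series that run through the identical sub-band pipeline (the count
series' slow fluctuations are what the 0.3–4 Hz band captures; that band is
typically the informative one for spiking activity, and all requested bands
are evaluated and reported). The baseline is a multi-class regularized LDA
on 200 ms spike counts stepped by 100 ms, with covariance shrinkage
$\gamma = 0.5$ toward the scaled identity.

## The synthetic generator

No public recordings accompany the task, so the package ships a generator
(`sim_config()` / `simulate_session()` / `simulate_spikes()`) that plants
precisely the structure the decoder claims to exploit, with known ground
truth:

* **Slow component.** `delta_sources` (default 6) band-limited (0.3–4 Hz)
  Gaussian source signals with fixed random spatial patterns are mixed into
  channels with direction-dependent gains: von Mises bumps (concentration
  `kappa = 2`) centered on equally spaced preferred angles, normalized so
  total slow power is direction-independent — the information lives in the
  covariance pattern, not in power. Mixing depth `delta_effect = 0.8`
  interpolates between untuned and fully tuned mixing. The planted
  covariance therefore varies smoothly and 360°-periodically with
  direction, with diametrically opposite directions maximally different
  (`analytic_delta_covariance()` exposes the closed form).
* **Fast component.** Independent 48–200 Hz carriers per channel carry a
  cosine-tuned envelope gain, $b_c(1 + d\cos(\theta - \phi_c) r(t))$ with
  depth `gamma_depth = 0.5` and random per-channel preferred angles.
* **Task gating.** Both effects follow one ramp $r(t)$: zero through the
  800 ms baseline, a fraction `delay_leak` from cue onset (600 ms cue,
  900 ms delay), rising linearly over the final 300 ms before movement
  onset to full strength through the 1000 ms movement epoch. Gating the
  slow mixing by the same ramp as the envelope gain is a deliberate choice:
  it gives the generator a single, controllable information onset, which is
  what the time-course properties test. `delay_leak` turns the weak
  delay-period information on and off as a ground-truth dial.
* **Noise.** Spatially correlated pink noise (`common_noise_frac = 0.3`
  shared across channels, SD `noise_sigma = 0.5`), plus an optional 60 Hz
  sinusoid on chosen channels for exercising the line-noise screen.
* **Spikes.** Inhomogeneous Poisson units with rate
  $r_u = \text{base} \cdot (1 + \text{mod}\cos(\theta - \theta_u)) \cdot r(t)$,
  preferred directions uniform. Note the ramp multiplies the whole rate, so
  units are silent before the cue; the closed-form expected count over any
  window is the rate times the ramp integral, which the tests verify.

Default geometry is 32 channels and 40 trials per direction — desk-scale,
while past the ~30-channel knee where accuracy gains flatten. Amplitudes
(`delta_amp = 1`, `gamma_amp = 0.5` against noise SD 0.5) put the planted
effects comfortably above the noise floor; this is a *strong-effect*
regime by construction.

**What passing tests do and do not show.** The generator produces Gaussian,
stationary-per-epoch signals with an idealized ramp and exactly periodic
direction tuning. Real LFP has non-Gaussian transients, electrode
cross-talk, behavioral variability in movement onset, and session-scale
non-stationarity far richer than the phase/gain jitter `drift_session()`
applies. Recovery of planted structure validates the *implementation* —
that the pipeline extracts direction-dependent covariance and envelope
tuning when present — not the biological effect sizes; absolute accuracies
on real recordings are not reproducible from synthetic data and are not
claimed.

## Problem sizes used by the shipped checks

The package's own verification runs use: the full default geometry
(32 channels × 320 trials, 10×10-fold CV) for the recovery and
chance-control checks; 16 channels for the two movement-aligned
sliding-window runs (15 window positions, 10×2-fold CV each, one run at
`delay_leak = 0` and one at 0.3); and 10-channel, 10-trial-per-class
sessions for module-level tests. These sizes were chosen so the complete
suite exercises every stage at the study's trial geometry while remaining
runnable on a laptop in a few minutes.

## Numerical conventions and degenerate inputs

* Direction is stored as an integer class index 0..K−1; angles only ever
  arise as index × 360/K, avoiding float-angle equality issues.
* The trial container stores float32 on disk; round-trips are exact at that
  precision, and identical inputs produce byte-identical files.
* Envelope tensors are non-negative by construction; the 0.3–4 Hz band
  keeps its sign.
* Zero-variance projections (constant channels) raise an error in feature
  extraction; the CSP solver refuses near-singular composite covariances
  with a message pointing at the shrinkage control.
* Constant-angle sequences in $\rho_T$ return flagged zeros; zero-variance
  score vectors in the corrected t-test return t = 0, p = 1 (no difference)
  or a signed infinite t (constant nonzero difference).
* The line-noise screen compares mean power in ±1 Hz around the line
  frequency against the channel's median broadband power (default ratio
  10). It never re-enables channels already masked. For signals with
  genuine gamma-band structure the appropriate threshold is higher, since
  the median PSD of a 1/f-plus-bands spectrum is small; screening is off
  by default and is a convenience, not a claim.

## Known limitations

* The decoder classifies one target direction per trial; trajectory
  decoding (which would need short windows and recursive CSP updates) is
  out of scope.
* Multi-class CSP variants (joint diagonalization), dense random ECOC
  codes, and probabilistic margin calibration are not implemented.
* Spectral estimation for the diagnostic time-frequency maps is a plain
  Hann-window STFT (256 ms, 75% overlap); no multitaper or wavelet option.
* The streaming/real-time path is absent by design; all computations are
  trial-batch.
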