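#' Parameters of the synthetic SSVEP generator
#'
#' The generator emulates a six-target frequency/phase-tagged experiment:
#' each trial contains a steady-state response at the cued frequency and its
#' harmonics, phase-locked to stimulation onset up to a trial-wise wrapped
#' normal phase jitter, spatially spread over channels by a mixing vector,
#' on top of 1/f-colored background noise (optionally with an alpha-band
#' sinusoid).
#'
#' `snr` is the per-channel amplitude ratio of the fundamental to the
#' background noise on a channel with unit mixing weight: the noise trace
#' has the RMS of a unit-amplitude sinusoid, and the evoked waveform is
#' scaled by `snr`, so a channel with mixing weight `m` sees a fundamental
#' whose RMS is `snr * m` times the noise RMS. `snr = Inf` disables the
#' noise entirely (unit-amplitude signal).
#'
#' @param n_channels Number of channels.
#' @param fs Sampling rate in Hz. Defaults to 500 Hz, the pipeline's
#'   post-downsampling rate; use 1024 Hz to exercise the resampling path.
#' @param trial_duration Trial length in seconds.
#' @param n_harmonics Number of harmonics in the evoked response.
#' @param harmonic_decay Amplitude factor applied per harmonic step.
#' @param snr Amplitude ratio described above (`>= 0`, may be `Inf`).
#' @param phase_jitter_sd Circular SD (radians) of the trial-wise phase
#'   jitter; the jitter is wrapped normal, whose circular SD equals the
#'   underlying normal SD.
#' @param mixing_mode `"localized"` (ECoG-like: energy concentrated on a
#'   source channel) or `"diffuse"` (scalp-like: smooth spread).
#' @param noise_alpha_power Amplitude of a 10-Hz background sinusoid with
#'   random phase per channel, relative to the noise RMS (0 disables).
#' @param seed Integer seed; all randomness in [simulate_session()] derives
#'   from it.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_channels = 8, fs = 500, trial_duration = 4,
                              n_harmonics = 3, harmonic_decay = 0.5,
                              snr = 1, phase_jitter_sd = 0.2,
                              mixing_mode = c("localized", "diffuse"),
                              noise_alpha_power = 0, seed = 1) {
  mixing_mode <- match.arg(mixing_mode)
  stopifnot(n_channels >= 1, fs > 0, trial_duration > 0, n_harmonics >= 1,
            harmonic_decay > 0, snr >= 0, phase_jitter_sd >= 0,
            noise_alpha_power >= 0)
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 trial_duration = trial_duration,
                 n_harmonics = as.integer(n_harmonics),
                 harmonic_decay = harmonic_decay, snr = snr,
                 phase_jitter_sd = phase_jitter_sd, mixing_mode = mixing_mode,
                 noise_alpha_power = noise_alpha_power,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

check_nyquist <- function(params, codebook) {
  fmax <- max(codebook$frequency) * params$n_harmonics
  if (params$fs <= 2 * fmax)
    stop(sprintf("fs = %g Hz violates Nyquist for harmonic content up to %g Hz",
                 params$fs, fmax))
}

#' Spatial mixing vector over channels
#'
#' `localized` concentrates weight on the source channel and its immediate
#' neighbors (narrow Gaussian kernel over the channel index, >= 80% of total
#' absolute weight on the source), emulating a focal cortical activation
#' under a subdural grid. `diffuse` spreads smooth positive weights over all
#' channels (wide kernel on a baseline, with gentle seeded variation),
#' emulating volume-conducted scalp topographies. Weights are normalized to
#' unit maximum.
#'
#' @param mode `"localized"` or `"diffuse"`.
#' @param n_channels Channel count.
#' @param source_channel Index of the dominant channel.
#' @param seed Seed for the diffuse mode's smooth variation.
#' @return Numeric weight vector of length `n_channels`, max 1.
#' @export
make_mixing <- function(mode = c("localized", "diffuse"), n_channels,
                        source_channel = ceiling(n_channels / 2), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_channels >= 1)
  if (source_channel < 1 || source_channel > n_channels)
    stop("`source_channel` out of range")
  idx <- seq_len(n_channels)
  if (mode == "localized") {
    w <- exp(-0.5 * ((idx - source_channel) / 0.45)^2)
  } else {
    w <- 0.35 + 0.65 * exp(-0.5 * ((idx - source_channel) / (0.6 * n_channels))^2)
    bump <- with_seed(seed, {
      k <- max(2, ceiling(n_channels / 4))
      ph <- runif(2, 0, 2 * pi)
      0.1 * (sin(2 * pi * idx / n_channels + ph[1]) +
             sin(2 * pi * 2 * idx / n_channels + ph[2])) / 2
    })
    w <- pmax(w * (1 + bump), 0.05)
  }
  w / max(w)
}

## 1/f^alpha-colored Gaussian noise, unit RMS, via spectral shaping.
colored_noise <- function(n, fs, alpha = 1) {
  white <- rnorm(n)
  X <- fft(white)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n              # symmetric shaping keeps X Hermitian
  f[1] <- 1                                 # DC bin is zeroed below anyway
  X <- X / f^(alpha / 2)
  X[1] <- 0
  x <- Re(fft(X, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

## Noiseless evoked waveform for one trial: sum of decaying harmonics with a
## common phase offset phi (the code phase plus trial jitter), sine-referenced.
ssvep_waveform <- function(f, phi, t, n_harmonics, harmonic_decay) {
  s <- 0
  for (h in seq_len(n_harmonics))
    s <- s + harmonic_decay^(h - 1) * sin(2 * pi * h * f * t + h * phi)
  s
}

#' Simulate a single trial
#'
#' Draws a trial-wise phase jitter (wrapped normal, circular SD
#' `params$phase_jitter_sd`), builds the harmonic evoked waveform for the
#' stimulus code, spreads it over channels with `mixing`, and adds
#' independent 1/f background noise per channel. Consumes the current R RNG
#' state, so it is deterministic given that state; [simulate_session()]
#' seeds it from `params$seed`.
#'
#' @param code One row of a codebook (list/row with `frequency`, `phase`).
#' @param params A [simulation_params()].
#' @param mixing Weight vector from [make_mixing()].
#' @return A `channel x sample` matrix.
#' @export
simulate_trial <- function(code, params, mixing) {
  stopifnot(inherits(params, "simulation_params"),
            length(mixing) == params$n_channels)
  if (params$fs <= 2 * code$frequency * params$n_harmonics)
    stop("Nyquist violation: raise fs or lower n_harmonics")
  n <- round(params$trial_duration * params$fs)
  t <- (seq_len(n) - 1) / params$fs
  eps <- if (params$phase_jitter_sd > 0) rnorm(1, 0, params$phase_jitter_sd) else 0
  wave <- ssvep_waveform(code$frequency, code$phase + eps, t,
                         params$n_harmonics, params$harmonic_decay)
  amp <- if (is.infinite(params$snr)) 1 else params$snr
  trial <- outer(mixing * amp, wave)
  if (!is.infinite(params$snr)) {
    noise_rms <- 1 / sqrt(2)                # RMS of a unit-amplitude sinusoid
    for (j in seq_len(params$n_channels)) {
      nz <- colored_noise(n, params$fs) * noise_rms
      if (params$noise_alpha_power > 0)
        nz <- nz + params$noise_alpha_power * noise_rms *
          sin(2 * pi * 10 * t + runif(1, 0, 2 * pi))
      trial[j, ] <- trial[j, ] + nz
    }
  }
  trial
}

#' Simulate a full experimental session
#'
#' Six targets, `cues_per_target` cues each (15 by default, i.e. 90 trials),
#' presented in pseudorandom order, with independent trial-wise phase
#' jitter. All randomness (trial order, jitter, noise) derives from
#' `params$seed`; identical parameters give a bit-identical epoch set.
#'
#' @param codebook A [make_codebook()] codebook.
#' @param cues_per_target Cues per target (default 15).
#' @param params A [simulation_params()].
#' @param mixing Optional mixing vector; defaults to
#'   `make_mixing(params$mixing_mode, params$n_channels, seed = params$seed)`.
#' @return An [epoch_set()] with the codebook attached.
#' @export
simulate_session <- function(codebook, cues_per_target = 15,
                             params = simulation_params(), mixing = NULL) {
  validate_codebook(codebook)
  stopifnot(cues_per_target >= 1)
  check_nyquist(params, codebook)
  mixing <- mixing %||% make_mixing(params$mixing_mode, params$n_channels,
                                    seed = params$seed)
  n <- round(params$trial_duration * params$fs)
  with_seed(params$seed, {
    order <- sample(rep(codebook$target_id, cues_per_target))
    out <- array(0, c(length(order), params$n_channels, n))
    for (i in seq_along(order)) {
      code <- codebook[codebook$target_id == order[i], ]
      out[i, , ] <- simulate_trial(code, params, mixing)
    }
    ep <- epoch_set(out, order, params$fs, codebook = codebook)
    attr(ep, "mixing") <- mixing
    attr(ep, "params") <- params
    ep
  })
}

#' Canned simulation regimes for the two recording modalities
#'
#' Two frozen generator settings used by the package's regime-comparison
#' experiments: `"localized"` emulates a high-SNR focal cortical recording
#' (subdural-grid-like; snr 4 on the source channel), `"diffuse"` a
#' low-SNR, spatially spread scalp recording (snr 0.15 per unit mixing
#' weight). Both use 8 channels, 3 harmonics with decay 0.5, and moderate
#' trial-wise phase jitter (0.2 rad) unless overridden.
#'
#' @param regime `"localized"` or `"diffuse"`.
#' @param ... Overrides passed to [simulation_params()] (e.g.
#'   `phase_jitter_sd`, `seed`).
#' @return A [simulation_params()] object.
#' @export
regime_params <- function(regime = c("localized", "diffuse"), ...) {
  regime <- match.arg(regime)
  defaults <- if (regime == "localized")
    list(n_channels = 8, snr = 4, mixing_mode = "localized")
  else
    list(n_channels = 8, snr = 0.15, mixing_mode = "diffuse")
  over <- list(...)
  do.call(simulation_params, utils::modifyList(defaults, over))
}
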