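#' Single-frequency phase estimate of a trial
#'
#' Computes the argument of the discrete Fourier component of `x` at
#' frequency `f`:
#' `atan2(sum(x * cos(2*pi*f*t)), sum(x * sin(2*pi*f*t)))`, with `t` in
#' seconds on the sample grid. The cosine sum is the first `atan2` argument,
#' so the convention is sine-referenced: a trace `sin(2*pi*f*t + theta)`
#' over whole periods yields `theta`. The result is normalized to
#' `[0, 2*pi)`.
#'
#' @param x Single-channel numeric sample vector.
#' @param f Frequency of interest in Hz (`f < fs/2`).
#' @param fs Sampling rate in Hz.
#' @return Phase in radians in `[0, 2*pi)`.
#' @export
estimate_phase <- function(x, f, fs) {
  if (length(x) == 0) stop("`x` must be a non-empty sample vector")
  if (f >= fs / 2) stop("`f` must be below Nyquist")
  t <- (seq_along(x) - 1) / fs
  atan2(sum(x * cos(2 * pi * f * t)), sum(x * sin(2 * pi * f * t))) %% (2 * pi)
}

#' Windowed periodogram (power spectral density)
#'
#' PSD estimate of a single-channel trace after applying a window whose
#' length equals the trace (Hamming by default). The FFT is zero-padded to
#' `nfft` so that short trials still have a frequency grid fine enough for
#' narrowband power readout.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param window `"hamming"` or `"rectangular"`.
#' @param nfft FFT length; defaults to the larger of `length(x)` and
#'   `4 * fs` (a 0.25 Hz grid).
#' @return An object of class `ssvep_spectrum`: list with `freq` (Hz, up to
#'   Nyquist) and `psd` (power per Hz).
#' @export
periodogram <- function(x, fs, window = c("hamming", "rectangular"),
                        nfft = NULL) {
  window <- match.arg(window)
  n <- length(x)
  if (n == 0) stop("`x` must be non-empty")
  w <- if (window == "hamming") 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
       else rep(1, n)
  if (n == 1) w <- 1
  nfft <- nfft %||% max(n, round(4 * fs))
  xw <- c(x * w, rep(0, nfft - n))
  X <- fft(xw)
  keep <- seq_len(nfft %/% 2 + 1)
  psd <- (Mod(X[keep])^2) / (fs * sum(w^2))
  structure(list(freq = (keep - 1) * fs / nfft, psd = psd),
            class = "ssvep_spectrum")
}

#' Narrowband power readout from a spectrum
#'
#' Mean PSD over the closed band `[f - width/2, f + width/2]` — the
#' narrowband power feature the naive decoder maximizes over the candidate
#' stimulation frequencies.
#'
#' @param spec An `ssvep_spectrum` from [periodogram()].
#' @param f Center frequency in Hz.
#' @param width Band width in Hz (default 0.5).
#' @return Mean power in the band.
#' @export
band_power <- function(spec, f, width = 0.5) {
  stopifnot(inherits(spec, "ssvep_spectrum"))
  lo <- f - width / 2; hi <- f + width / 2
  if (lo < min(spec$freq) - 1e-9 || hi > max(spec$freq) + 1e-9)
    stop(sprintf("band [%g, %g] Hz lies outside the spectrum range", lo, hi))
  sel <- spec$freq >= lo - 1e-9 & spec$freq <= hi + 1e-9
  if (!any(sel)) stop("no spectral bins inside the requested band")
  mean(spec$psd[sel])
}
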