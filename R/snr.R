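#' Narrowband signal-to-noise spectrum
#'
#' For each frequency of interest, the SNR is the mean periodogram power in
#' the 0.5-Hz band centered on the frequency, divided by the mean power in
#' the flanking bands (within +/- `flank` Hz of the frequency, excluding
#' the center band). For white noise this ratio is ~1 at every frequency;
#' a steady-state response produces a sharp peak at its stimulation
#' frequency and harmonics.
#'
#' @param x Single-channel sample vector, at least 2 s long (0.5-Hz
#'   resolution).
#' @param f_list Frequencies of interest in Hz.
#' @param fs Sampling rate in Hz.
#' @param width Center band width in Hz (default 0.5).
#' @param flank Half-width of the flanking region in Hz (default 1.5).
#' @param window Periodogram window (default `"hamming"`).
#' @return Data frame with columns `frequency` and `snr`.
#' @export
snr_spectrum <- function(x, f_list, fs, width = 0.5, flank = 1.5,
                         window = "hamming") {
  if (length(x) / fs < 2)
    stop("need at least 2 s of signal for 0.5-Hz resolution")
  spec <- periodogram(x, fs, window = window)
  snr <- vapply(f_list, function(f) {
    lo <- f - flank; hi <- f + flank
    if (lo < min(spec$freq) - 1e-9 || hi > max(spec$freq) + 1e-9)
      stop(sprintf("flanking band of %g Hz lies outside the spectrum", f))
    center <- spec$freq >= f - width / 2 - 1e-9 & spec$freq <= f + width / 2 + 1e-9
    side <- spec$freq >= lo - 1e-9 & spec$freq <= hi + 1e-9 & !center
    mean(spec$psd[center]) / mean(spec$psd[side])
  }, numeric(1))
  data.frame(frequency = f_list, snr = snr)
}
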