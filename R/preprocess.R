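#' Continuous multi-channel recording
#'
#' @param data Numeric `channel x sample` matrix.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character channel names.
#' @param events Data frame with columns `onset` (sample index, 1-based) and
#'   `target_id`, one row per cue.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, channel_labels = NULL, events = NULL) {
  stopifnot(is.matrix(data), fs > 0)
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("`channel_labels` length must equal the channel count")
  if (!is.null(events)) {
    stopifnot(all(c("onset", "target_id") %in% names(events)))
    if (any(events$onset < 1 | events$onset > ncol(data)))
      stop("event onsets must lie within the recording")
  }
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 events = events), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs,
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

#' Re-reference a recording
#'
#' Common average reference (CAR) subtracts the across-channel mean at every
#' time point — the standard montage for a subdural grid. The
#' `reference_channels` scheme subtracts the mean trace of the named
#' channels (e.g. the two mastoids, `c("TP9", "TP10")`) from every channel,
#' as is customary for scalp EEG.
#'
#' @param rec A [recording()].
#' @param scheme `"CAR"` or a character vector of reference channel names.
#' @return A re-referenced `recording`.
#' @export
rereference <- function(rec, scheme = "CAR") {
  stopifnot(inherits(rec, "recording"))
  if (identical(scheme, "CAR")) {
    ref <- colMeans(rec$data)
  } else {
    idx <- match(scheme, rec$channel_labels)
    if (anyNA(idx))
      stop("unknown reference channel(s): ",
           paste(scheme[is.na(idx)], collapse = ", "))
    ref <- colMeans(rec$data[idx, , drop = FALSE])
  }
  rec$data <- sweep(rec$data, 2, ref)
  rec
}

#' Classifier-specific filtering bands
#'
#' The pipeline stores the recording once per classifier-specific range:
#' 0.5-40 Hz for the naive Fourier/phase decoder, 4-20 Hz for the
#' spatiotemporal beamformer, and 8-70 / 16-70 Hz for the two filterbank-CCA
#' sub-bands.
#'
#' @param name Band identifier (used as the cache key).
#' @param low,high Band edges in Hz.
#' @param order Butterworth order (design order; zero-phase application
#'   doubles the effective order).
#' @return A `band_spec` list.
#' @export
band_spec <- function(name, low, high, order = 4) {
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  structure(list(name = name, low = low, high = high, order = order),
            class = "band_spec")
}

#' @rdname band_spec
#' @export
classifier_bands <- function() {
  list(naive     = band_spec("naive", 0.5, 40),
       stbf      = band_spec("stbf", 4, 20),
       fbcca_sb1 = band_spec("fbcca_sb1", 8, 70),
       fbcca_sb2 = band_spec("fbcca_sb2", 16, 70))
}

butter_band <- function(band, fs) {
  if (band$high >= fs / 2)
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)", band$high, fs / 2))
  signal::butter(band$order, c(band$low, band$high) / (fs / 2), type = "pass")
}

#' Band-pass filter a recording
#'
#' Fourth-order Butterworth band-pass, applied zero-phase (forward-backward)
#' by default so that the phase used by the decoders is not biased by the
#' filter's group delay; the analysis is offline, so non-causality is
#' acceptable. Causal single-pass filtering is available via
#' `zero_phase = FALSE`.
#'
#' @param rec A [recording()].
#' @param band A [band_spec()].
#' @param zero_phase Logical.
#' @return A filtered `recording`.
#' @export
bandpass <- function(rec, band, zero_phase = TRUE) {
  stopifnot(inherits(rec, "recording"), inherits(band, "band_spec"))
  bf <- butter_band(band, rec$fs)
  out <- rec$data
  for (j in seq_len(nrow(out))) {
    out[j, ] <- if (zero_phase) signal::filtfilt(bf, rec$data[j, ])
                else as.numeric(signal::filter(bf, rec$data[j, ]))
  }
  rec$data <- out
  rec
}

## Fourier-domain resampling of a single trace. Exactly preserves amplitude
## and phase of in-band components; assumes the trace is analysed as a whole
## (periodogram/decoder use), where edge leakage matches that of the
## original trace.
fft_resample <- function(x, n_out) {
  n_in <- length(x)
  if (n_out == n_in) return(x)
  X <- fft(x)
  Y <- complex(length.out = n_out)
  nh <- min(n_in, n_out) %/% 2
  Y[1] <- X[1]
  if (nh >= 1) Y[1 + seq_len(nh)] <- X[1 + seq_len(nh)]
  if (nh >= 2) Y[n_out + 1 - seq_len(nh - 1)] <- X[n_in + 1 - seq_len(nh - 1)]
  Re(fft(Y, inverse = TRUE)) / n_in
}

#' Cut a recording into stimulation-locked trials and resample
#'
#' One trial per event, starting at the event onset and lasting `duration`
#' seconds, anti-alias-resampled to `target_fs`. The default resampler works
#' in the Fourier domain (spectrum truncation), which preserves the phase of
#' in-band sinusoids to machine precision; `method = "polyphase"` uses
#' [signal::resample()] instead.
#'
#' @param rec A [recording()] with events.
#' @param duration Trial length in seconds (default 4).
#' @param target_fs Output sampling rate in Hz (default 500).
#' @param codebook Optional codebook attached to the result.
#' @param method `"fft"` or `"polyphase"`.
#' @return An [epoch_set()] at `target_fs`.
#' @export
epoch_and_resample <- function(rec, duration = 4, target_fs = 500,
                               codebook = NULL, method = c("fft", "polyphase")) {
  stopifnot(inherits(rec, "recording"))
  method <- match.arg(method)
  if (is.null(rec$events) || nrow(rec$events) == 0)
    stop("recording has no events to epoch around")
  n_in <- round(duration * rec$fs)
  n_out <- round(duration * target_fs)
  ends <- rec$events$onset + n_in - 1
  if (any(bad <- ends > ncol(rec$data)))
    stop("event(s) at onset ", paste(rec$events$onset[bad], collapse = ", "),
         " extend beyond the end of the recording")
  nt <- nrow(rec$events); nc <- nrow(rec$data)
  out <- array(0, c(nt, nc, n_out))
  for (i in seq_len(nt)) {
    seg <- rec$data[, rec$events$onset[i] + seq_len(n_in) - 1, drop = FALSE]
    for (j in seq_len(nc)) {
      out[i, j, ] <- if (method == "fft") fft_resample(seg[j, ], n_out)
                     else resample_polyphase(seg[j, ], target_fs, rec$fs, n_out)
    }
  }
  epoch_set(out, rec$events$target_id, target_fs, rec$channel_labels, codebook)
}

resample_polyphase <- function(x, target_fs, fs, n_out) {
  r <- rational_approx(target_fs / fs)
  y <- signal::resample(x, r[1], r[2])
  length(y) <- n_out
  y[is.na(y)] <- 0
  y
}

## Small continued-fraction rational approximation p/q of a ratio.
rational_approx <- function(ratio, max_den = 4096) {
  best <- c(1, 1); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(ratio * q)
    if (p < 1) next
    e <- abs(p / q - ratio)
    if (e < err - 1e-15) { best <- c(p, q); err <- e }
    if (e < 1e-12) break
  }
  best
}
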