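#' Labeled single-trial epochs
#'
#' The pipeline's trial container: a `trial x channel x sample` array of
#' signal values together with per-trial target labels, the sampling rate,
#' channel labels and the codebook that generated (or cued) the trials.
#' Band-filtered copies of the data are kept in a band-keyed cache (see
#' [epochs_bandpass()]), mirroring a workflow in which the continuous
#' recording is stored once per classifier-specific filtering range.
#'
#' @param data Numeric array, `trial x channel x sample`.
#' @param labels Integer vector of target ids, one per trial.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of channel names (defaults to
#'   `ch01`, `ch02`, ...).
#' @param codebook A [make_codebook()] codebook covering all labels.
#' @param bands Optional named list of band-filtered copies of `data`
#'   (same dimensions), keyed by band name.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, fs, channel_labels = NULL, codebook = NULL,
                      bands = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  d <- dim(data)
  if (length(labels) != d[1])
    stop("`labels` must have one entry per trial (", d[1], "), got ", length(labels))
  if (!is.null(codebook) && !all(labels %in% codebook$target_id))
    stop("every label must be present in the codebook")
  if (fs <= 0) stop("`fs` must be positive")
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%02d", seq_len(d[2]))
  if (length(channel_labels) != d[2])
    stop("`channel_labels` length must equal the channel count")
  structure(
    list(data = data, labels = as.integer(labels), fs = fs,
         channel_labels = channel_labels, codebook = codebook, bands = bands),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz (%.3g s)\n",
              d[1], d[2], d[3], x$fs, d[3] / x$fs))
  cat("  labels:", paste(sprintf("%d:%d", sort(unique(x$labels)),
                                 tabulate(x$labels)[sort(unique(x$labels))]),
                         collapse = " "), "\n")
  if (length(x$bands)) cat("  cached bands:", paste(names(x$bands), collapse = ", "), "\n")
  invisible(x)
}

#' Epoch-set dimensions
#'
#' @param ep An [epoch_set()].
#' @return Trial, channel or sample count.
#' @export
n_trials <- function(ep) dim(ep$data)[1]

#' @rdname n_trials
#' @export
n_channels <- function(ep) dim(ep$data)[2]

#' @rdname n_trials
#' @export
n_samples <- function(ep) dim(ep$data)[3]

#' Subset an epoch set
#'
#' @param ep An [epoch_set()].
#' @param trials,channels Integer indices (or `NULL` to keep all).
#'   Band caches are subset consistently.
#' @return An `epoch_set`.
#' @export
subset_epochs <- function(ep, trials = NULL, channels = NULL) {
  trials <- trials %||% seq_len(n_trials(ep))
  channels <- channels %||% seq_len(n_channels(ep))
  take <- function(a) a[trials, channels, , drop = FALSE]
  epoch_set(take(ep$data), ep$labels[trials], ep$fs,
            ep$channel_labels[channels], ep$codebook,
            bands = lapply(ep$bands, take))
}

#' Crop trials to a shorter stimulation length
#'
#' Truncates every trial (and every cached band-filtered copy) to the first
#' `round(length_s * fs)` samples. Labels are unchanged. Used to evaluate
#' decoders at short stimulation lengths while training remains full-length.
#'
#' @param ep An [epoch_set()].
#' @param length_s Desired length in seconds, `0 < length_s <=` trial duration.
#' @return An `epoch_set` with shorter trials.
#' @export
crop_trials <- function(ep, length_s) {
  dur <- n_samples(ep) / ep$fs
  if (!is.numeric(length_s) || length(length_s) != 1 || length_s <= 0)
    stop("`length_s` must be a single positive number")
  if (length_s > dur + 1e-9)
    stop(sprintf("cannot crop to %g s: trials are only %g s long", length_s, dur))
  n_keep <- min(round(length_s * ep$fs), n_samples(ep))
  take <- function(a) a[, , seq_len(n_keep), drop = FALSE]
  epoch_set(take(ep$data), ep$labels, ep$fs, ep$channel_labels, ep$codebook,
            bands = lapply(ep$bands, take))
}

#' Band-filter an epoch set and cache the result
#'
#' Applies a zero-phase Butterworth band-pass (see [bandpass()]) to every
#' trial and channel and stores the result under the band's name in the
#' epoch set's band cache. Re-filtering an already-cached band is a no-op.
#'
#' @param ep An [epoch_set()].
#' @param band A [band_spec()].
#' @param zero_phase Forward-backward filtering (default) or causal.
#' @return The `epoch_set` with `ep$bands[[band$name]]` filled.
#' @export
epochs_bandpass <- function(ep, band, zero_phase = TRUE) {
  if (!is.null(ep$bands[[band$name]])) return(ep)
  bf <- butter_band(band, ep$fs)
  out <- ep$data
  nt <- n_trials(ep); nc <- n_channels(ep)
  for (i in seq_len(nt)) {
    for (j in seq_len(nc)) {
      x <- ep$data[i, j, ]
      out[i, j, ] <- if (zero_phase) signal::filtfilt(bf, x)
                     else as.numeric(signal::filter(bf, x))
    }
  }
  ep$bands[[band$name]] <- out
  ep
}

## Return the trial x channel x sample array for `band`, filtering on the
## fly when no cached copy exists.
epochs_band_data <- function(ep, band) {
  ep$bands[[band$name]] %||% epochs_bandpass(ep, band)$bands[[band$name]]
}

## One trial (channel x sample matrix) in a given band.
trial_matrix <- function(ep, i, band = NULL) {
  a <- if (is.null(band)) ep$data else epochs_band_data(ep, band)
  matrix(a[i, , ], nrow = dim(a)[2], ncol = dim(a)[3])
}
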