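#' Train the naive Fourier/phase decoder
#'
#' For each target the per-trial phase at the target's stimulation
#' frequency is estimated on one analysis channel with [estimate_phase()],
#' and the circular mean over training trials becomes the target's phase
#' template. Trials are taken from the 0.5-40 Hz band copy.
#'
#' @param train An [epoch_set()] with a codebook, at least one trial per
#'   target.
#' @param channel Analysis channel index (default 1).
#' @return A `naive_model`: phase templates per target plus the codebook.
#' @export
fit_naive <- function(train, channel = 1) {
  cb <- train$codebook
  if (is.null(cb)) stop("training epochs need a codebook")
  if (channel < 1 || channel > n_channels(train)) stop("`channel` out of range")
  missing <- setdiff(cb$target_id, unique(train$labels))
  if (length(missing))
    stop("no training trials for target(s): ", paste(missing, collapse = ", "))
  band <- classifier_bands()$naive
  train <- epochs_bandpass(train, band)
  templates <- vapply(cb$target_id, function(id) {
    idx <- which(train$labels == id)
    f <- cb$frequency[cb$target_id == id]
    circ_mean(vapply(idx, function(i)
      estimate_phase(trial_matrix(train, i, band)[channel, ], f, train$fs),
      numeric(1)))
  }, numeric(1))
  structure(list(templates = stats::setNames(templates, cb$target_id),
                 codebook = cb, channel = channel, fs = train$fs,
                 band = band),
            class = c("naive_model", "ssvep_model"))
}

## Classify one band-filtered single-trial matrix.
predict_naive_trial <- function(x, model) {
  cb <- model$codebook
  spec <- periodogram(x, model$fs, window = "hamming")
  freqs <- unique(cb$frequency)
  pw <- vapply(freqs, function(f) band_power(spec, f, 0.5), numeric(1))
  f_hat <- freqs[which.max(pw)]            # ties: first (lowest-target) frequency
  phi_hat <- estimate_phase(x, f_hat, model$fs)
  cand <- cb$target_id[cb$frequency == f_hat]
  d <- abs(circ_diff(model$templates[as.character(cand)], phi_hat))
  cand[which.min(d)]                       # ties: lowest target_id
}

#' @export
predict_epochs.naive_model <- function(model, ep, ...) {
  ep <- epochs_bandpass(ep, model$band)
  vapply(seq_len(n_trials(ep)), function(i)
    predict_naive_trial(trial_matrix(ep, i, model$band)[model$channel, ],
                        model),
    numeric(1))
}

#' Classify trials with a fitted decoder model
#'
#' @param model A fitted model from [fit_naive()], [fit_fbcca()],
#'   [fit_stbf()] or [fit_decoder()].
#' @param ep An [epoch_set()] of (possibly cropped) test trials.
#' @param ... Unused.
#' @return Integer vector of predicted target ids, one per trial.
#' @export
predict_epochs <- function(model, ep, ...) UseMethod("predict_epochs")
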