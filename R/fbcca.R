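#' Sub-band weighting of the filterbank
#'
#' The n-th sub-band's contribution is weighted by
#' `w(n) = n^(-a) + b`, emphasizing the lower sub-band (which carries the
#' fundamental) while retaining harmonic-dominated sub-bands.
#'
#' @param n Sub-band index (1-based).
#' @param a,b Weighting constants (defaults 1.25 and 0.25).
#' @return Numeric weight.
#' @export
fb_weight <- function(n, a = 1.25, b = 0.25) n^(-a) + b

#' Train the filterbank CCA decoder with individual calibration
#'
#' For each sub-band (8-70 Hz and 16-70 Hz by default) and each target, the
#' across-trial average of the band-filtered full-length training trials is
#' stored as a calibration template; harmonic references ([build_reference()]
#' with `h` harmonics) complete the model.
#'
#' @param train Full-length training [epoch_set()] with a codebook.
#' @param codebook Codebook (defaults to the epoch set's).
#' @param subbands List of [band_spec()] sub-bands.
#' @param h Number of reference harmonics (default 3).
#' @param weights Numeric `c(a, b)` of the sub-band weighting `n^(-a) + b`.
#' @param reference_only If `TRUE`, prediction ignores the calibration
#'   templates and uses the plain reference-CCA score (ablation mode).
#' @return An `fbcca_model`.
#' @export
fit_fbcca <- function(train, codebook = train$codebook,
                      subbands = classifier_bands()[c("fbcca_sb1", "fbcca_sb2")],
                      h = 3, weights = c(a = 1.25, b = 0.25),
                      reference_only = FALSE) {
  if (is.null(codebook)) stop("training epochs need a codebook")
  missing <- setdiff(codebook$target_id, unique(train$labels))
  if (length(missing))
    stop("no training trials for target(s): ", paste(missing, collapse = ", "))
  if (any(codebook$frequency * h >= train$fs / 2))
    stop("reference harmonics exceed Nyquist; lower `h`")
  for (sb in subbands) train <- epochs_bandpass(train, sb)
  templates <- lapply(subbands, function(sb) {
    lapply(stats::setNames(codebook$target_id, codebook$target_id), function(id) {
      idx <- which(train$labels == id)
      a <- train$bands[[sb$name]][idx, , , drop = FALSE]
      matrix(apply(a, c(2, 3), mean), nrow = dim(a)[2])
    })
  })
  names(templates) <- vapply(subbands, `[[`, "", "name")
  structure(list(templates = templates, subbands = subbands, h = h,
                 weights = weights, codebook = codebook, fs = train$fs,
                 reference_only = reference_only),
            class = c("fbcca_model", "ssvep_model"))
}

## Per-trial fbCCA scores for every target. `refs` is a list (by target id)
## of reference matrices already cropped to the trial length.
fbcca_scores <- function(trial_bands, model, refs) {
  cb <- model$codebook
  nb <- length(model$subbands)
  a <- model$weights[["a"]]; b <- model$weights[["b"]]
  scores <- numeric(nrow(cb))
  n <- ncol(trial_bands[[1]])
  for (ti in seq_len(nrow(cb))) {
    id <- cb$target_id[ti]
    rho <- 0
    for (sb in seq_len(nb)) {
      X <- trial_bands[[sb]]
      cc <- cca_first(X, refs[[as.character(id)]])
      r1 <- cc$rho
      if (model$reference_only) {
        feat <- r1
      } else {
        tmpl <- model$templates[[sb]][[as.character(id)]][, seq_len(n), drop = FALSE]
        px <- as.vector(crossprod(cc$wx, X))
        pt <- as.vector(crossprod(cc$wx, tmpl))
        r2 <- if (sd(px) < 1e-14 || sd(pt) < 1e-14) 0 else cor(px, pt)
        feat <- sign(r1) * r1^2 + sign(r2) * r2^2
      }
      # sign-preserving square keeps anti-correlated targets from ranking high
      rho <- rho + fb_weight(sb, a, b) * sign(feat) * feat^2
    }
    scores[ti] <- rho
  }
  stats::setNames(scores, cb$target_id)
}

#' @export
predict_epochs.fbcca_model <- function(model, ep, ...) {
  cb <- model$codebook
  n <- n_samples(ep)
  if (n / ep$fs < 1 / min(cb$frequency))
    stop("trials are shorter than one period of the slowest target frequency")
  for (sb in model$subbands) ep <- epochs_bandpass(ep, sb)
  refs <- lapply(stats::setNames(cb$target_id, cb$target_id), function(id)
    build_reference(cb$frequency[cb$target_id == id], model$h, n, ep$fs))
  vapply(seq_len(n_trials(ep)), function(i) {
    tb <- lapply(model$subbands, function(sb) trial_matrix(ep, i, sb))
    s <- fbcca_scores(tb, model, refs)
    cb$target_id[which.max(s)]             # ties: lowest target_id
  }, numeric(1))
}
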