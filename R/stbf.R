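#' Cut a trial into period-length segments
#'
#' Splits a `channel x sample` trial into consecutive, non-overlapping
#' segments whose length equals one period of frequency `f`. When the
#' period is not an integer number of samples, segment boundaries are
#' placed at `round(k * fs / f)` (drift-free) and each segment is
#' `floor(fs / f)` samples long, so the cutting stays phase-locked to
#' stimulation onset over the whole trial.
#'
#' @param trial Numeric `channel x sample` matrix.
#' @param f Expected frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @return A `channel x period_sample x segment` array with attributes
#'   `frequency` and `period_samples`.
#' @export
cut_segments <- function(trial, f, fs) {
  if (!is.matrix(trial)) trial <- matrix(trial, nrow = 1)
  n_per <- floor(fs / f)
  if (ncol(trial) < n_per)
    stop("trial is shorter than one period of ", f, " Hz")
  starts <- integer(0)
  k <- 0
  repeat {
    s <- round(k * fs / f) + 1
    if (s + n_per - 1 > ncol(trial)) break
    starts <- c(starts, s)
    k <- k + 1
  }
  out <- array(0, c(nrow(trial), n_per, length(starts)))
  for (i in seq_along(starts))
    out[, , i] <- trial[, starts[i] + seq_len(n_per) - 1, drop = FALSE]
  attr(out, "frequency") <- f
  attr(out, "period_samples") <- n_per
  out
}

## Flatten a channel x period matrix by concatenating its rows.
flatten_rows <- function(m) as.vector(t(m))

#' Shrinkage-regularized covariance
#'
#' Sample covariance of the rows of `x`, shrunk toward its diagonal with
#' the Schafer-Strimmer analytic shrinkage intensity (or a user-supplied
#' `lambda`), plus a tiny ridge so that the zero-variance limit stays
#' invertible (yielding a multiple of the identity).
#'
#' @param x Numeric `observations x variables` matrix.
#' @param lambda `"auto"` or a value in `[0, 1]`.
#' @return List with the regularized `sigma` and the `lambda` used.
#' @export
shrink_cov <- function(x, lambda = "auto") {
  k <- nrow(x); p <- ncol(x)
  if (k < 2) stop("need at least two observations")
  S <- cov(x)
  if (identical(lambda, "auto")) {
    xc <- sweep(x, 2, colMeans(x))
    ## var-hat of each off-diagonal S entry (Schafer & Strimmer 2005)
    w2 <- crossprod(xc^2) / k - (crossprod(xc) / k)^2
    varS <- k / (k - 1)^3 * w2 * k   # = k/(k-1)^3 * sum((w - wbar)^2)
    off <- !diag(p)
    den <- sum(S[off]^2)
    lambda <- if (den <= 0) 1 else max(0, min(1, sum(varS[off]) / den))
  }
  sigma <- (1 - lambda) * S
  diag(sigma) <- diag(S)
  ridge <- max(1e-10 * mean(diag(S)), 1e-12)
  diag(sigma) <- diag(sigma) + ridge
  list(sigma = sigma, lambda = lambda)
}

#' LCMV weights for one activation pattern
#'
#' The linearly-constrained minimum-variance solution
#' `w = solve(Sigma, a) / (a' solve(Sigma, a))`, which passes the pattern
#' `a` with unit gain (`a' w = 1`) while minimizing output variance.
#'
#' @param a Flattened activation pattern (numeric vector).
#' @param sigma Covariance matrix (`length(a)` square).
#' @return Weight vector `w` with `sum(a * w) = 1`.
#' @export
lcmv_weights <- function(a, sigma) {
  if (sqrt(sum(a^2)) < 1e-300) stop("activation pattern is zero; cannot constrain")
  sa <- tryCatch(solve(sigma, a),
                 error = function(e) stop("covariance is singular; ",
                                          "use shrinkage regularization", call. = FALSE))
  as.vector(sa / sum(a * sa))
}

#' Train the spatiotemporal LCMV beamformer bank
#'
#' For each target, all 4-20 Hz band-filtered training trials of that
#' target are cut into period-length segments at the target's frequency
#' ([cut_segments()]); the mean segment is the spatiotemporal activation
#' pattern, the flattened segments are the observations whose
#' shrinkage-regularized covariance enters the LCMV solution
#' ([lcmv_weights()]).
#'
#' @param train Full-length training [epoch_set()] with a codebook.
#' @param codebook Codebook (defaults to the epoch set's).
#' @param shrinkage `"auto"` (analytic) or a fixed value in `[0, 1]`.
#' @return A `beamformer_bank` with per-target pattern `A`, weights `w` and
#'   the shrinkage used.
#' @export
fit_stbf <- function(train, codebook = train$codebook, shrinkage = "auto") {
  if (is.null(codebook)) stop("training epochs need a codebook")
  missing <- setdiff(codebook$target_id, unique(train$labels))
  if (length(missing))
    stop("no training trials for target(s): ", paste(missing, collapse = ", "))
  band <- classifier_bands()$stbf
  train <- epochs_bandpass(train, band)
  filters <- lapply(stats::setNames(codebook$target_id, codebook$target_id),
                    function(id) {
    f <- codebook$frequency[codebook$target_id == id]
    idx <- which(train$labels == id)
    segs <- lapply(idx, function(i)
      cut_segments(trial_matrix(train, i, band), f, train$fs))
    segs <- array(unlist(segs), dim = c(dim(segs[[1]])[1:2],
                                        sum(vapply(segs, function(s) dim(s)[3], 0))))
    A <- apply(segs, c(1, 2), mean)
    E <- t(apply(segs, 3, flatten_rows))
    a <- flatten_rows(A)
    sc <- shrink_cov(E, shrinkage)
    w <- lcmv_weights(a, sc$sigma)
    list(A = A, w = w, a = a, frequency = f, lambda = sc$lambda)
  })
  structure(list(filters = filters, codebook = codebook, fs = train$fs,
                 band = band),
            class = c("beamformer_bank", "ssvep_model"))
}

#' @export
predict_epochs.beamformer_bank <- function(model, ep, ...) {
  cb <- model$codebook
  if (n_samples(ep) / ep$fs < 1 / min(cb$frequency))
    stop("trials are shorter than one period of the slowest target frequency")
  ep <- epochs_bandpass(ep, model$band)
  vapply(seq_len(n_trials(ep)), function(i) {
    x <- trial_matrix(ep, i, model$band)
    y <- vapply(as.character(cb$target_id), function(id) {
      flt <- model$filters[[id]]
      segs <- cut_segments(x, flt$frequency, ep$fs)
      s <- flatten_rows(apply(segs, c(1, 2), mean))
      sum(s * flt$w)                       # raw score, not absolute value
    }, numeric(1))
    cb$target_id[which.max(y)]             # ties: lowest target_id
  }, numeric(1))
}
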