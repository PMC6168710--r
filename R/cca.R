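#' Harmonic sine/cosine reference matrix
#'
#' Builds the `2h x n_samples` reference used by CCA-based SSVEP decoding:
#' unit-amplitude `sin`/`cos` pairs at the stimulation frequency and its
#' first `h` harmonics, on the sample grid.
#'
#' @param f Fundamental frequency in Hz.
#' @param h Number of harmonics (default 3).
#' @param n_samples Number of samples.
#' @param fs Sampling rate in Hz.
#' @return Matrix with rows `sin(f), cos(f), sin(2f), cos(2f), ...`.
#' @export
build_reference <- function(f, h = 3, n_samples, fs) {
  if (h * f >= fs / 2)
    stop(sprintf("harmonic %d of %g Hz is at or above Nyquist", h, f))
  t <- (seq_len(n_samples) - 1) / fs
  Y <- matrix(0, 2 * h, n_samples)
  for (k in seq_len(h)) {
    Y[2 * k - 1, ] <- sin(2 * pi * k * f * t)
    Y[2 * k, ]     <- cos(2 * pi * k * f * t)
  }
  Y
}

## First canonical correlation between the rows of X and the rows of Y,
## via the covariance-based generalized eigenproblem. Returns the
## correlation and the X-side weight vector. Small ridge terms guard
## against near-singular covariance.
cca_first <- function(X, Y) {
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  sx <- sqrt(rowMeans(Xc^2))
  if (all(sx < 1e-14)) {
    warning("constant (zero-variance) X in canonical correlation; returning 0")
    return(list(rho = 0, wx = rep(0, nrow(X))))
  }
  Cxx <- tcrossprod(Xc) / n
  Cyy <- tcrossprod(Yc) / n
  Cxy <- tcrossprod(Xc, Yc) / n
  rx <- 1e-10 * mean(diag(Cxx)) + 1e-300
  ry <- 1e-10 * mean(diag(Cyy)) + 1e-300
  diag(Cxx) <- diag(Cxx) + rx
  diag(Cyy) <- diag(Cyy) + ry
  M <- solve(Cxx, Cxy %*% solve(Cyy, t(Cxy)))
  e <- eigen(M)
  rho2 <- Re(e$values[1])
  wx <- Re(e$vectors[, 1])
  list(rho = sqrt(max(0, min(1, rho2))), wx = wx)
}

#' First canonical correlation
#'
#' Maximal Pearson correlation attainable between a linear combination of
#' the rows of `X` (e.g. channels of a trial) and a linear combination of
#' the rows of `Y` (e.g. a harmonic reference from [build_reference()]).
#'
#' @param X Numeric matrix, `variables x samples`.
#' @param Y Numeric matrix, `variables x samples`, same sample count.
#' @return Scalar in `[0, 1]`. A zero-variance `X` yields 0 with a warning.
#' @export
canonical_correlation <- function(X, Y) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1)
  if (ncol(X) != ncol(Y)) stop("`X` and `Y` must have the same sample count")
  if (nrow(X) < 1 || nrow(Y) < 1) stop("both inputs need at least one row")
  cca_first(X, Y)$rho
}
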