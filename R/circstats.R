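#' Circular summary statistics
#'
#' `circ_mean()` is the direction of the mean resultant vector, in
#' `[0, 2*pi)`. `circ_diff()` is the signed circular difference wrapped to
#' `(-pi, pi]`. `circular_sd()` is `sqrt(-2 * log(Rbar))` with `Rbar` the
#' mean resultant length; it is 0 when all angles coincide and `Inf` when
#' the resultant vanishes.
#'
#' @param angles Numeric vector of angles in radians.
#' @param a,b Angles in radians.
#' @return Radians.
#' @export
circ_mean <- function(angles) {
  if (length(angles) == 0) stop("need at least one angle")
  atan2(mean(sin(angles)), mean(cos(angles))) %% (2 * pi)
}

#' @rdname circ_mean
#' @export
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' @rdname circ_mean
#' @export
circular_sd <- function(angles) {
  if (length(angles) < 2) stop("need at least two angles")
  rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  if (rbar <= .Machine$double.eps) return(Inf)
  sqrt(-2 * log(min(rbar, 1)))
}

#' Two-sample Kuiper test for circular data
#'
#' Rotation-invariant analogue of the two-sample Kolmogorov-Smirnov test:
#' the statistic is `V = max(D) - min(D)` where `D` is the difference of the
#' two empirical CDFs along the circle, which makes `V` independent of the
#' choice of cut point. The p-value uses the standard asymptotic series with
#' the effective-sample-size correction.
#'
#' @param a,b Numeric vectors of angles in radians (each of length >= 5).
#' @return List with `statistic` (V) and `p.value`.
#' @export
kuiper_two_sample <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 5 || n2 < 5) stop("both samples must contain at least 5 angles")
  a <- a %% (2 * pi); b <- b %% (2 * pi)
  vals <- sort(unique(c(a, b)))
  ca <- cumsum(tabulate(match(sort(a), vals), length(vals))) / n1
  cb <- cumsum(tabulate(match(sort(b), vals), length(vals))) / n2
  d <- c(0, ca - cb)
  V <- max(d) - min(d)
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * V
  p <- if (lambda < 0.4) 1 else {
    j <- 1:100
    min(1, max(0, 2 * sum((4 * j^2 * lambda^2 - 1) * exp(-2 * j^2 * lambda^2))))
  }
  list(statistic = V, p.value = p)
}

#' Paired Wilcoxon signed-rank comparison with Bonferroni correction
#'
#' Two-tailed Wilcoxon signed-rank test on paired accuracy vectors, with the
#' significance threshold divided by the number of comparisons (Bonferroni):
#' e.g. alpha 0.05 over 3 pairwise classifier comparisons gives a threshold
#' of 0.0167. When every paired difference is zero the p-value is 1 by
#' convention.
#'
#' @param a,b Paired numeric vectors (equal length >= 5).
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_comparisons Number of comparisons in the family (default 1).
#' @return List with `p.value`, `threshold` (`alpha / n_comparisons`) and
#'   `significant`.
#' @export
paired_wilcoxon <- function(a, b, alpha = 0.05, n_comparisons = 1) {
  if (length(a) != length(b)) stop("`a` and `b` must be paired (equal length)")
  if (length(a) < 5) stop("need at least 5 pairs")
  p <- if (all(a == b)) 1 else
    suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
  thr <- alpha / n_comparisons
  list(p.value = p, threshold = thr, significant = p < thr)
}
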