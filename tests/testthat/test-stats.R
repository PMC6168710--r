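test_that("circular SD has its closed-form values and symmetries", {
  expect_equal(circular_sd(rep(1.3, 5)), 0)
  expect_equal(circular_sd(c(0, pi / 2)), sqrt(-2 * log(sqrt(2) / 2)),
               tolerance = 1e-12)
  expect_equal(circular_sd(c(0, pi / 2)), 0.8326, tolerance = 1e-4)
  a <- c(0.2, 1.1, 5.9, 3.0)
  expect_equal(circular_sd(a), circular_sd((a + 2.5) %% (2 * pi)),
               tolerance = 1e-12)
  expect_equal(circular_sd(c(0, pi)), Inf)
  expect_error(circular_sd(1), "two angles")
})

test_that("the Kuiper test accepts identical samples and rejects opposed ones", {
  a <- seq(0.1, 2 * pi, length.out = 20)
  same <- kuiper_two_sample(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  d <- ssveptag:::with_seed(55, list(x = rnorm(50, 0, 0.4) %% (2 * pi),
                                     y = (rnorm(50, pi, 0.4)) %% (2 * pi)))
  opposed <- kuiper_two_sample(d$x, d$y)
  expect_lt(opposed$p.value, 0.01)

  # rotation invariance of the statistic
  rot <- kuiper_two_sample((d$x + 1.7) %% (2 * pi), (d$y + 1.7) %% (2 * pi))
  expect_equal(rot$statistic, opposed$statistic, tolerance = 1e-12)

  expect_error(kuiper_two_sample(1:3, 1:10), "at least 5")
})

test_that("paired Wilcoxon applies the Bonferroni threshold", {
  res <- paired_wilcoxon(runif(8), runif(8), alpha = 0.05, n_comparisons = 3)
  expect_equal(res$threshold, 0.05 / 3)
  expect_equal(round(res$threshold, 4), 0.0167)

  a <- c(0.5, 0.6, 0.55, 0.7, 0.65, 0.6, 0.5, 0.58)
  expect_false(paired_wilcoxon(a, a)$significant)
  expect_equal(paired_wilcoxon(a, a)$p.value, 1)

  res2 <- paired_wilcoxon(a, a + 0.1)
  expect_lt(res2$p.value, 0.05)
})

test_that("SNR spectra are flat for white noise and peak at injected tones", {
  fs <- 500
  snrs <- ssveptag:::with_seed(60, replicate(100, {
    x <- rnorm(4 * fs)
    snr_spectrum(x, c(13, 20), fs, window = "rectangular")$snr
  }))
  # flat-spectrum expectation: mean SNR ~ 1
  expect_equal(mean(snrs), 1, tolerance = 0.15)

  t <- (0:1999) / fs
  x <- ssveptag:::with_seed(61, 2 * sin(2 * pi * 13 * t) + rnorm(2000))
  s <- snr_spectrum(x, c(13, 14), fs)
  expect_gt(s$snr[1] / s$snr[2], 10)

  # zero-amplitude stimulation: finite SNR, no division blow-up
  xz <- ssveptag:::with_seed(62, rnorm(2000))
  expect_true(all(is.finite(snr_spectrum(xz, c(11, 13, 15), fs)$snr)))
  expect_error(snr_spectrum(rnorm(400), 13, fs), "at least 2 s")
})

test_that("imputation reproduces an exact linear control relationship", {
  controls <- control_table(subject = rep(1:4, each = 2),
                            session = rep(1:2, 4),
                            phase_sd = seq(0.2, 0.9, length.out = 8),
                            mean_accuracy = 0.95 - 0.5 * seq(0.2, 0.9,
                                                             length.out = 8),
                            decoder = "naive")
  res <- impute_patient_accuracy(controls, c(s1 = 0.4, s2 = 0.75), seed = 5)
  expect_equal(res$n_iterations, rep(100, 2))
  expect_equal(res$imputed_mean, 0.95 - 0.5 * c(0.4, 0.75), tolerance = 1e-9)
  expect_equal(res$imputed_sd, c(0, 0), tolerance = 1e-9)
})

test_that("imputed draws honor the predictive interval around a control point", {
  set.seed(9)
  x <- seq(0.1, 1.1, length.out = 12)
  y <- pmin(1, pmax(0, 0.9 - 0.4 * x + rnorm(12, 0, 0.03)))
  controls <- control_table(1:12, 1, x, y, "stbf")
  fit <- lm(y ~ x)
  s <- summary(fit)$sigma
  res <- impute_patient_accuracy(controls, c(sA = x[5]), n_iter = 400, seed = 6)
  expect_lt(abs(res$imputed_mean - y[5]), 2 * s + 0.1)
  expect_gt(res$imputed_sd, 0)
  expect_error(impute_patient_accuracy(control_table(1:3, 1, c(0.2, 0.2, 0.2),
                                                     c(0.5, 0.6, 0.7), "x"),
                                       0.3),
               "distinct")
})
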