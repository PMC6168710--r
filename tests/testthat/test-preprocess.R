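make_rec <- function(n_ch = 3, n_s = 4000, fs = 500, seed = 1) {
  dat <- ssveptag:::with_seed(seed, matrix(rnorm(n_ch * n_s), n_ch))
  recording(dat, fs)
}

test_that("common average referencing removes the across-channel mean", {
  rec <- recording(matrix(3.7, 2, 100), fs = 500)
  out <- rereference(rec, "CAR")
  expect_true(all(out$data == 0))

  rec2 <- make_rec()
  out2 <- rereference(rec2, "CAR")
  expect_lt(max(abs(colSums(out2$data))), 1e-9 * max(abs(rec2$data)))
  # idempotent
  expect_equal(rereference(out2, "CAR")$data, out2$data)
})

test_that("reference-channel scheme subtracts the named channels' mean", {
  dat <- rbind(sin(1:200), cos(1:200), 0, 0)
  rec <- recording(dat, 500, channel_labels = c("O1", "O2", "TP9", "TP10"))
  out <- rereference(rec, c("TP9", "TP10"))
  expect_equal(out$data, dat)   # zero reference leaves data unchanged
  expect_error(rereference(rec, c("TP9", "XX")), "unknown reference")
})

test_that("band-pass preserves in-band and rejects out-of-band sinusoids", {
  fs <- 500
  t <- (0:3999) / fs
  in_band <- recording(matrix(sin(2 * pi * 13 * t), 1), fs)
  out <- bandpass(in_band, band_spec("stbf", 4, 20))
  mid <- 1000:3000
  expect_equal(max(abs(out$data[1, mid])), 1, tolerance = 0.02)

  low <- recording(matrix(sin(2 * pi * 2 * t), 1), fs)
  out2 <- bandpass(low, band_spec("fbcca_sb1", 8, 70))
  expect_lt(max(abs(out2$data[1, mid])), 0.1)

  zero <- recording(matrix(0, 1, 4000), fs)
  expect_true(all(bandpass(zero, band_spec("naive", 0.5, 40))$data == 0))

  expect_error(bandpass(in_band, band_spec("bad", 8, 300)), "Nyquist")
})

test_that("zero-phase filtering does not bias the estimated phase", {
  fs <- 500
  t <- (0:1999) / fs
  rec <- recording(matrix(sin(2 * pi * 13 * t + 1.1), 1), fs)
  out <- bandpass(rec, band_spec("naive", 0.5, 40))
  expect_equal(estimate_phase(out$data[1, ], 13, fs), 1.1, tolerance = 0.02)
})

test_that("epoching cuts trials at event onsets and resamples to 500 Hz", {
  fs <- 1024
  n <- fs * 40
  t <- (0:(n - 1)) / fs
  theta <- 0.9
  dat <- matrix(sin(2 * pi * 13 * t + theta), 1)
  onsets <- seq(1, by = 4 * fs + 512, length.out = 9)
  rec <- recording(dat, fs, events = data.frame(onset = onsets,
                                                target_id = rep(1:3, 3)))
  ep <- epoch_and_resample(rec, duration = 4, target_fs = 500)
  expect_equal(dim(ep$data), c(9, 1, 2000))
  expect_equal(ep$fs, 500)
  expect_equal(ep$labels, rep(1:3, 3))

  # resampling preserves the single-bin phase of an in-band sinusoid
  ph_orig <- estimate_phase(dat[1, onsets[2] + 0:(4 * fs - 1)], 13, fs)
  ph_res <- estimate_phase(ep$data[2, 1, ], 13, 500)
  expect_lt(abs(circ_diff(ph_res, ph_orig)), 0.05)
})

test_that("epoching at the target rate is an identity", {
  fs <- 500
  dat <- matrix(rnorm(fs * 10), 1)
  rec <- recording(dat, fs, events = data.frame(onset = c(1, 2001),
                                                target_id = c(1, 2)))
  ep <- epoch_and_resample(rec, duration = 4, target_fs = 500)
  expect_equal(ep$data[1, 1, ], dat[1, 1:2000], tolerance = 1e-9)
})

test_that("events that do not fit in the recording are rejected", {
  rec <- recording(matrix(0, 1, 1000), 500,
                   events = data.frame(onset = 900, target_id = 1))
  expect_error(epoch_and_resample(rec, duration = 4), "beyond the end")
})

test_that("cropping truncates trials without touching labels", {
  ep <- noiseless_session(cues = 2)
  cr <- crop_trials(ep, 0.25)
  expect_equal(dim(cr$data)[3], 125)
  expect_equal(cr$labels, ep$labels)
  expect_equal(crop_trials(ep, 4)$data, ep$data)
  expect_error(crop_trials(ep, 5), "cannot crop")
  expect_error(crop_trials(ep, 0))
})

test_that("re-referencing commutes with trial cropping", {
  dat <- ssveptag:::with_seed(2, array(rnorm(6 * 3 * 1000), c(6, 3, 1000)))
  ep <- epoch_set(dat, rep(1:3, 2), fs = 500)
  # CAR applied per trial matrix equals cropping before/after
  car_trial <- function(m) sweep(m, 2, colMeans(m))
  a <- car_trial(matrix(dat[1, , 1:500], 3))
  b <- car_trial(matrix(dat[1, , ], 3))[, 1:500]
  expect_equal(a, b)
})

test_that("band filtering commutes with cropping away from trial edges", {
  fs <- 500
  x <- ssveptag:::with_seed(4, as.numeric(signal::filtfilt(
    signal::butter(2, 0.3), rnorm(2000))))
  bf <- ssveptag:::butter_band(band_spec("stbf", 4, 20), fs)
  full_then_crop <- signal::filtfilt(bf, x)[1:1000]
  crop_then_filter <- signal::filtfilt(bf, x[1:1000])
  interior <- 250:750
  expect_equal(full_then_crop[interior], crop_then_filter[interior],
               tolerance = 0.05)
})
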