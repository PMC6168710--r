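test_that("mixing vectors match their regime geometry", {
  expect_equal(make_mixing("localized", 1, 1), 1)

  w <- make_mixing("localized", 48, source_channel = 36)
  expect_equal(which.max(w), 36)
  expect_true(all(w[-36] < w[36]))
  expect_gte(w[36] / sum(abs(w)), 0.8)
  expect_equal(max(w), 1)

  wd <- make_mixing("diffuse", 32, seed = 5)
  expect_true(all(wd > 0))
  expect_lt(max(wd) / median(wd), 10)
  expect_equal(max(wd), 1)

  expect_error(make_mixing("blob", 8))
  expect_error(make_mixing("localized", 8, source_channel = 9), "out of range")
})

test_that("a noiseless jitter-free trial is the closed-form harmonic sum", {
  p <- simulation_params(n_channels = 1, snr = Inf, phase_jitter_sd = 0)
  code <- list(frequency = 13, phase = 0)
  tr <- simulate_trial(code, p, mixing = 1)
  t <- (0:1999) / 500
  expected <- sin(2 * pi * 13 * t) + 0.5 * sin(2 * pi * 26 * t) +
    0.25 * sin(2 * pi * 39 * t)
  expect_equal(as.numeric(tr), expected, tolerance = 1e-12)
})

test_that("the noiseless fundamental carries the code phase", {
  p <- simulation_params(n_channels = 2, snr = Inf, phase_jitter_sd = 0)
  for (ph in c(0, 2 * pi / 3, 4 * pi / 3, pi)) {
    tr <- simulate_trial(list(frequency = 14, phase = ph), p, mixing = c(1, 0.5))
    expect_equal(estimate_phase(tr[1, ], 14, p$fs), ph %% (2 * pi),
                 tolerance = 1e-6)
  }
})

test_that("simulation is deterministic given the seed", {
  p <- simulation_params(n_channels = 3, snr = 0.8, phase_jitter_sd = 0.3,
                         seed = 99)
  ep1 <- simulate_session(make_codebook(1), cues_per_target = 2, params = p)
  ep2 <- simulate_session(make_codebook(1), cues_per_target = 2, params = p)
  expect_identical(ep1$data, ep2$data)
  expect_identical(ep1$labels, ep2$labels)
})

test_that("sessions have the designed trial counts and uniform labels", {
  ep <- simulate_session(make_codebook(2),
                         params = simulation_params(n_channels = 2, snr = 2,
                                                    seed = 7))
  expect_equal(n_trials(ep), 90)
  expect_true(all(tabulate(ep$labels, 6) == 15))

  ep2 <- simulate_session(make_codebook(3), cues_per_target = 2,
                          params = simulation_params(n_channels = 1, seed = 3))
  expect_equal(n_trials(ep2), 12)
  expect_true(all(tabulate(ep2$labels, 6) == 2))
})

test_that("noiseless trials peak at the code frequency in the periodogram", {
  p <- simulation_params(n_channels = 1, snr = Inf, phase_jitter_sd = 0)
  for (f in c(11, 13, 15)) {
    tr <- simulate_trial(list(frequency = f, phase = 1), p, mixing = 1)
    spec <- periodogram(tr[1, ], p$fs, window = "rectangular", nfft = 2000)
    expect_equal(spec$freq[which.max(spec$psd)], f)
  }
})

test_that("phases recover the code phase at high snr and no jitter", {
  p <- simulation_params(n_channels = 4, snr = 10, phase_jitter_sd = 0, seed = 8)
  cb <- make_codebook(2)
  mix <- make_mixing("localized", 4, source_channel = 2)
  ep <- simulate_session(cb, cues_per_target = 2, params = p, mixing = mix)
  for (i in seq_len(n_trials(ep))) {
    f <- cb$frequency[ep$labels[i]]
    ph <- cb$phase[ep$labels[i]]
    err <- abs(circ_diff(estimate_phase(ep$data[i, 2, ], f, p$fs), ph))
    expect_lt(err, 0.1)
  }
})

test_that("circular SD of estimated phases recovers the jitter parameter", {
  jit <- 0.5
  p <- simulation_params(n_channels = 1, snr = 20, phase_jitter_sd = jit,
                         seed = 13)
  code <- list(frequency = 13, phase = pi / 3)
  phases <- ssveptag:::with_seed(1301, vapply(1:220, function(i) {
    tr <- simulate_trial(code, p, 1)
    estimate_phase(tr[1, ], 13, p$fs)
  }, numeric(1)))
  expect_equal(circular_sd(phases), jit, tolerance = 0.15)
})

test_that("invalid simulation settings are rejected", {
  expect_error(simulation_params(snr = -1))
  p <- simulation_params(n_channels = 1, fs = 80, n_harmonics = 3)
  expect_error(simulate_trial(list(frequency = 30, phase = 0), p, 1), "Nyquist")
  expect_error(simulate_session(make_codebook(1), params = p), "Nyquist")
})
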