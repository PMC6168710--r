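## Small synthetic sessions and decoder stubs shared across tests.

noiseless_session <- function(session_id = 2, cues = 3, n_channels = 4,
                              seed = 42, fs = 500) {
  simulate_session(make_codebook(session_id), cues_per_target = cues,
                   params = simulation_params(n_channels = n_channels, fs = fs,
                                              snr = Inf, phase_jitter_sd = 0,
                                              seed = seed))
}

noisy_session <- function(session_id = 2, cues = 5, n_channels = 4,
                          snr = 1, jitter = 0.2, seed = 42,
                          mixing_mode = "localized") {
  simulate_session(make_codebook(session_id), cues_per_target = cues,
                   params = simulation_params(n_channels = n_channels,
                                              snr = snr,
                                              phase_jitter_sd = jitter,
                                              mixing_mode = mixing_mode,
                                              seed = seed))
}

## Always predicts the true label (reads it off the epoch set).
perfect_stub <- function() {
  decoder("custom", fit = function(train) {
    list(predict = function(model, ep) ep$labels)
  })
}

## Uniform-random predictions over the codebook targets.
random_stub <- function() {
  decoder("custom", fit = function(train) {
    ids <- train$codebook$target_id
    list(predict = function(model, ep) sample(ids, n_trials(ep), replace = TRUE))
  })
}

## Records the trial lengths seen at fit and predict time.
instrumented_stub <- function(log_env) {
  decoder("custom", fit = function(train) {
    log_env$fit_lengths <- c(log_env$fit_lengths, dim(train$data)[3])
    list(predict = function(model, ep) {
      log_env$test_lengths <- c(log_env$test_lengths, dim(ep$data)[3])
      ep$labels
    })
  })
}

## Bind 1 x c x s arrays along the first (trial) dimension.
abind3 <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]])) parts <- parts[[1]]
  d <- dim(parts[[1]])
  out <- array(0, c(length(parts), d[2], d[3]))
  for (i in seq_along(parts)) out[i, , ] <- parts[[i]]
  out
}

## Definition-level re-implementation of the naive decoding rule, with the
## DFT computed by direct summation: Hamming-window the trace, evaluate the
## spectral power by explicit sums on the zero-padded bin grid, average the
## bins in the 0.5-Hz band around each candidate frequency, pick the
## frequency with the largest power, estimate the phase by the two explicit
## Fourier sums, and choose the candidate target with the smallest absolute
## circular phase difference.
brute_force_naive <- function(x, model, cb, fs) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  xw <- x * w
  nfft <- max(n, round(4 * fs))
  bin_power <- function(k) {
    ang <- -2 * pi * k * (0:(n - 1)) / nfft
    (sum(xw * cos(ang))^2 + sum(xw * sin(ang))^2) / (fs * sum(w^2))
  }
  freqs <- unique(cb$frequency)
  pw <- vapply(freqs, function(f) {
    ks <- which((0:(nfft %/% 2)) * fs / nfft >= f - 0.25 - 1e-9 &
                (0:(nfft %/% 2)) * fs / nfft <= f + 0.25 + 1e-9) - 1
    mean(vapply(ks, bin_power, numeric(1)))
  }, numeric(1))
  f_hat <- freqs[which.max(pw)]
  t <- (0:(n - 1)) / fs
  phi <- atan2(sum(x * cos(2 * pi * f_hat * t)),
               sum(x * sin(2 * pi * f_hat * t))) %% (2 * pi)
  cand <- cb$target_id[cb$frequency == f_hat]
  diffs <- vapply(cand, function(id) {
    d <- (model$templates[[as.character(id)]] - phi) %% (2 * pi)
    abs(if (d > pi) d - 2 * pi else d)
  }, numeric(1))
  cand[which.min(diffs)]
}
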