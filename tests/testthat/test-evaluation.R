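test_that("stratified folds cover every trial once with balanced labels", {
  labels <- rep(1:6, each = 15)
  folds <- stratified_folds(labels, 5, seed = 3)
  expect_length(folds, 90)
  expect_true(all(folds %in% 1:5))
  for (lb in 1:6) {
    counts <- tabulate(folds[labels == lb], 5)
    expect_lte(diff(range(counts)), 1)
  }
  expect_error(stratified_folds(rep(1:6, 2), 5), "stratification impossible")
})

test_that("a perfect decoder scores 1 at every length and a random one near chance", {
  ep <- noiseless_session(cues = 5, n_channels = 1)
  cfg <- eval_config(n_folds = 5, lengths = c(0.5, 1, 2), seed = 2)
  cv <- crossval_curve(ep, perfect_stub(), cfg)
  expect_equal(cv$accuracy, rep(1, 3))

  set.seed(404)
  cvr <- crossval_curve(ep, random_stub(), cfg)
  # 90 predictions pooled per length; binomial(90, 1/6) 99.9% interval
  expect_true(all(cvr$accuracy > 0.02 & cvr$accuracy < 0.40))
})

test_that("training always sees full-length trials; only tests are cropped", {
  ep <- noiseless_session(cues = 5, n_channels = 1)
  log_env <- new.env()
  log_env$fit_lengths <- integer(0); log_env$test_lengths <- integer(0)
  cfg <- eval_config(n_folds = 5, lengths = c(0.25, 1, 4), seed = 2)
  crossval_curve(ep, instrumented_stub(log_env), cfg)
  expect_equal(log_env$fit_lengths, rep(2000, 5))
  expect_setequal(unique(log_env$test_lengths), c(125, 500, 2000))
})

test_that("the default protocol evaluates 16 lengths from 0.25 to 4 s", {
  cfg <- eval_config()
  expect_length(cfg$lengths, 16)
  expect_equal(range(cfg$lengths), c(0.25, 4))
  expect_equal(diff(cfg$lengths), rep(0.25, 15))
  expect_error(eval_config(n_folds = 1), "folds")
})

test_that("single-electrode mapping finds the localized source channel", {
  ep <- noisy_session(cues = 5, n_channels = 4, snr = 2, jitter = 0.1,
                      seed = 30)
  cfg <- eval_config(n_folds = 5, lengths = c(1, 2, 4), seed = 4)
  tab <- single_electrode_map(ep, decoder("naive"), cfg)
  expect_equal(nrow(tab), 4)
  # localized mixing puts the source on channel ceiling(4/2) = 2
  expect_equal(attr(tab, "best_channel"), 2)

  one <- single_electrode_map(subset_epochs(ep, channels = 2),
                              decoder("naive"), cfg)
  expect_equal(nrow(one), 1)
})

test_that("per-channel accuracies spread less under diffuse mixing", {
  cfg <- eval_config(n_folds = 5, lengths = c(1, 4), seed = 4)
  ep_loc <- noisy_session(cues = 5, n_channels = 4, snr = 1, jitter = 0.1,
                          seed = 31, mixing_mode = "localized")
  ep_dif <- noisy_session(cues = 5, n_channels = 4, snr = 1, jitter = 0.1,
                          seed = 31, mixing_mode = "diffuse")
  v_loc <- var(single_electrode_map(ep_loc, decoder("naive"), cfg)$mean_accuracy)
  v_dif <- var(single_electrode_map(ep_dif, decoder("naive"), cfg)$mean_accuracy)
  expect_lt(v_dif, v_loc)
})

test_that("greedy selection stops at a perfect single channel and improves monotonically", {
  ep <- noiseless_session(cues = 5, n_channels = 3)
  cfg <- eval_config(n_folds = 5, lengths = c(1, 2), seed = 5)
  g <- suppressWarnings(greedy_select(ep, decoder("stbf"), cfg))
  expect_length(g$channels, 1)
  expect_equal(g$objective, 1)

  ep2 <- noisy_session(cues = 5, n_channels = 4, snr = 0.15, jitter = 0.2,
                       seed = 33, mixing_mode = "diffuse")
  g2 <- suppressWarnings(greedy_select(ep2, decoder("naive"), cfg))
  expect_true(all(diff(g2$objective) > 0))
  # never worse than the best single electrode (step 1 is the best single)
  best_single <- max(vapply(1:4, function(j)
    mean_accuracy(crossval_curve(subset_epochs(ep2, channels = j),
                                 decoder("naive"), cfg)), numeric(1)))
  expect_gte(max(g2$objective) + 1e-12, best_single)
  expect_warning(greedy_select(ep, decoder("stbf"),
                               eval_config(5, c(1), seed = 1)), "optimistic")
})
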