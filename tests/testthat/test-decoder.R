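test_that("a small session fits end to end and exposes the model surface", {
  ses <- small_session(seed = 11, n_trials = 6)
  res <- decode_session(ses, train_trials = 4, seed = 11)
  fit <- res$model

  expect_s3_class(fit, "snn_decoder")
  expect_named(fit$populations,
               c("emg1", "emg2", "kin1", "kin2", "movement_onset"))
  expect_true(all(vapply(fit$populations, function(p)
    length(p$members), integer(1)) >= 1))

  expect_output(print(fit), "Spiking neural network decoder")
  s <- summary(fit)
  expect_s3_class(s, "summary.snn_decoder")
  expect_equal(nrow(s$table), 5)
  cf <- coef(fit)
  expect_true(all(c("population", "cluster", "w_readout") %in% names(cf)))

  scores <- res$scores
  expect_equal(nrow(scores), 4)
  expect_true(all(is.finite(scores$r_max)))
  expect_true(all(abs(scores$r_max) <= 1))
  expect_true(all(abs(scores$lag_at_max_ms) <= 100))
})

test_that("prediction is insensitive to all-zero input beyond flat output", {
  ses <- small_session(seed = 12, n_trials = 6)
  res <- decode_session(ses, train_trials = 4, seed = 12)
  te <- res$test_session
  flat <- continuous_signal(
    matrix(0, nrow(te$inputs$values), ncol(te$inputs$values),
           dimnames = list(NULL, te$inputs$channel_labels)),
    te$inputs$sample_rate)
  p <- predict(res$model, flat, events = te$events)
  expect_true(all(p$q == 0))
  expect_true(all(vapply(p$readout_spikes, length, integer(1)) == 0))
  # decoded signals stay at each channel's initial value
  for (lb in res$model$target_labels) {
    init <- res$model$thresholds_tg$channels[[lb]]$initial
    expect_true(all(p$decoded$values[, lb] == init))
  }
})

test_that("streaming prediction is identical to batch prediction", {
  ses <- small_session(seed = 13, n_trials = 6)
  res <- decode_session(ses, train_trials = 4, seed = 13)
  te <- res$test_session
  pb <- predict(res$model, te$inputs, events = te$events, mode = "batch")
  ps <- predict(res$model, te$inputs, events = te$events, mode = "streaming")
  expect_identical(pb$q, ps$q)
  expect_identical(pb$currents, ps$currents)
  expect_identical(pb$member_spikes, ps$member_spikes)
  expect_identical(pb$decoded$values, ps$decoded$values)
  expect_equal(length(ps$latency), nrow(te$inputs$values))
  expect_true(all(ps$latency >= 0))
})

test_that("serialisation round-trips the model and all its predictions", {
  ses <- small_session(seed = 14, n_trials = 6)
  res <- decode_session(ses, train_trials = 4, seed = 14)
  te <- res$test_session
  p1 <- predict(res$model, te$inputs, events = te$events)

  f <- withr::local_tempfile(fileext = ".json")
  save_decoder(res$model, f)
  m2 <- load_decoder(f)
  p2 <- predict(m2, te$inputs, events = te$events)
  expect_identical(p1$q, p2$q)
  expect_identical(p1$member_spikes, p2$member_spikes)
  expect_identical(p1$decoded$values, p2$decoded$values)

  # the reloaded model serialises to the same bytes
  f2 <- withr::local_tempfile(fileext = ".json")
  save_decoder(m2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("refitting with one seed is deterministic, another seed differs", {
  ses <- small_session(seed = 15, n_trials = 6)
  r1 <- decode_session(ses, train_trials = 4, seed = 15)
  r2 <- decode_session(ses, train_trials = 4, seed = 15)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  save_decoder(r1$model, f1); save_decoder(r2$model, f2)
  expect_identical(readLines(f1), readLines(f2))

  r3 <- decode_session(ses, train_trials = 4, seed = 16)
  expect_false(identical(r1$model$reservoir$weights,
                         r3$model$reservoir$weights))
})

test_that("misaligned inputs and montage problems are rejected", {
  ses <- small_session(seed = 17, n_trials = 4)
  short <- continuous_signal(ses$targets$values[1:100, ], 100)
  expect_error(snn_decoder(ses$inputs, short, ses$events,
                           montage = ses$montage), "share length")
  # unknown channels with no montage entry
  expect_error(snn_decoder(ses$inputs, ses$targets, ses$events),
               "montage")
})
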