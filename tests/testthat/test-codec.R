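test_that("threshold computation matches hand-derived values", {
  # d = |diff| = (2, 1, 4); population sd
  e <- compute_threshold(c(0, 2, 3, 7), c = 0)
  expect_equal(e$th, 7 / 3)
  expect_equal(e$mean, 7 / 3)
  expect_equal(e$initial, 0)

  d <- c(2, 1, 4)
  sd_pop <- sqrt(mean((d - mean(d))^2))
  e2 <- compute_threshold(c(0, 2, 3, 7), c = 0.5)
  expect_equal(e2$th, 7 / 3 + 0.5 * sd_pop)

  # constant channel: zero differences, zero threshold
  expect_equal(compute_threshold(c(5, 5, 5, 5), c = 3)$th, 0)

  expect_error(compute_threshold(5, c = 1), "2 samples")
  expect_error(compute_threshold(c(1, NA, 3), c = 1), "finite")
})

test_that("encoding emits signed spikes at threshold crossings", {
  sig <- continuous_signal(cbind(a = c(0, 2, 3, 7)), sample_rate = 1)
  th <- encoding_thresholds(sig, c = 0)
  ra <- encode_spikes(sig, th)
  expect_equal(ra$trains$a$times, 3)       # only |diff|=4 >= 7/3
  expect_equal(ra$trains$a$signs, 1L)

  # negative step
  sig2 <- continuous_signal(cbind(b = c(3, 0)), sample_rate = 1)
  th2 <- structure(list(channels = list(b = list(th = 2, initial = 3)),
                        sample_rate = 1), class = "encoding_thresholds")
  ra2 <- encode_spikes(sig2, th2)
  expect_equal(ra2$trains$b$signs, -1L)
  un <- unsigned_spikes(ra2)
  expect_null(un$trains$b$signs)
  expect_equal(un$trains$b$times, ra2$trains$b$times)

  # zero-threshold (constant) channel stays silent
  sig3 <- continuous_signal(cbind(c = c(5, 5, 5, 5)), sample_rate = 1)
  ra3 <- encode_spikes(sig3, encoding_thresholds(sig3, c = 1))
  expect_equal(ra3$trains$c$n, 0L)
})

test_that("decoding reconstructs the staircase from signed spikes", {
  th <- structure(list(channels = list(a = list(th = 7 / 3, initial = 0)),
                       sample_rate = 1), class = "encoding_thresholds")
  ra <- spike_raster(list(spike_train(3, duration = 3, signs = 1L)),
                     labels = "a", sample_rate = 1)
  dec <- decode_spikes(ra, th, 4)
  expect_equal(unname(dec$values[, 1]), c(0, 0, 0, 7 / 3))

  # empty raster: constant at the initial value
  ra0 <- spike_raster(list(spike_train(numeric(0), 3)), labels = "a",
                      sample_rate = 1)
  th5 <- structure(list(channels = list(a = list(th = 1, initial = 5)),
                        sample_rate = 1), class = "encoding_thresholds")
  expect_equal(unname(decode_spikes(ra0, th5, 4)$values[, 1]), rep(5, 4))

  # unsigned spikes require the explicit all-positive opt-in
  ra1 <- spike_raster(list(spike_train(2, 3)), labels = "a",
                      sample_rate = 1)
  expect_error(decode_spikes(ra1, th5, 4), "all_positive")
  expect_equal(unname(decode_spikes(ra1, th5, 4,
                                    sign_policy = "all_positive")$values[, 1]),
               c(5, 5, 6, 6))
})

test_that("round trip is exact for staircases stepping by the threshold", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(20:60, 1)
    # dyadic arithmetic keeps successive differences exactly +/- step
    step <- sample(c(0.5, 1, 2), 1)
    init <- step * sample(-5:5, 1)
    x <- init + cumsum(sample(c(-step, step), n, replace = TRUE))
    sig <- continuous_signal(cbind(ch = c(init, x)), sample_rate = 10)
    th <- encoding_thresholds(sig, c = runif(1, 0, 2))  # all diffs equal step
    expect_equal(th$channels$ch$th, step)
    dec <- decode_spikes(encode_spikes(sig, th), th, n + 1)
    expect_equal(unname(dec$values[, 1]), unname(sig$values[, 1]))
  }
})

test_that("raising the encoding factor never increases the spike count", {
  set.seed(42)
  x <- cumsum(rnorm(300))
  sig <- continuous_signal(cbind(ch = x), sample_rate = 100)
  counts <- vapply(c(0, 0.5, 1, 1.5, 2, 3), function(cc)
    encode_spikes(sig, encoding_thresholds(sig, cc))$trains$ch$n, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("encoding is causal: early samples fix early spikes", {
  set.seed(7)
  x <- cumsum(rnorm(100))
  sig <- continuous_signal(cbind(ch = x), sample_rate = 100)
  th <- encoding_thresholds(sig, c = 0.5)
  full <- encode_spikes(sig, th)$trains$ch$times
  # perturbing the tail cannot change spikes before the perturbation
  x2 <- x; x2[81:100] <- x2[81:100] + rnorm(20, 0, 5)
  sig2 <- continuous_signal(cbind(ch = x2), sample_rate = 100)
  part <- encode_spikes(sig2, th)$trains$ch$times
  expect_identical(full[full < 0.80], part[part < 0.80])
})

test_that("threshold and raster files round-trip", {
  sig <- continuous_signal(cbind(a = rnorm(50), b = rnorm(50)),
                           sample_rate = 100)
  th <- encoding_thresholds(sig, c = 0.7)
  f <- withr::local_tempfile(fileext = ".json")
  write_thresholds_json(th, f)
  th2 <- read_thresholds_json(f)
  expect_equal(th2$channels$a$th, th$channels$a$th)
  expect_equal(th2$sample_rate, 100)

  ra <- encode_spikes(sig, th)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_raster_csv(ra, f2)
  ra2 <- read_raster_csv(f2)
  expect_equal(ra2$labels, ra$labels)
  expect_equal(ra2$trains$a$times, ra$trains$a$times)
  expect_equal(ra2$trains$b$signs, ra$trains$b$signs)

  f3 <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(sig, f3)
  sig2 <- read_signal_csv(f3)
  expect_equal(sig2$sample_rate, 100)
  expect_equal(unname(sig2$values), unname(sig$values))
})
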