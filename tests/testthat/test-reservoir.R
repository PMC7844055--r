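test_that("template construction is deterministic and partitioned", {
  t1 <- brain_template()
  t2 <- brain_template()
  expect_identical(t1, t2)
  expect_gt(nrow(t1), 100)
  expect_false(anyDuplicated(t1[c("x", "y", "z")]) > 0)
  expect_lte(length(unique(t1$region)), 16)

  cl <- extract_clusters(t1)
  expect_equal(sort(unlist(cl, use.names = FALSE)), seq_len(nrow(t1)))
  expect_true(all(lengths(cl) > 0))
  expect_identical(names(cl), sort(names(cl)))

  expect_error(brain_template(resolution = 1000), "fewer than 2")
  expect_error(brain_template_from_coords(
    data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 0),
               region = c("a", "b"))), "duplicate")
})

test_that("input mapping is nearest-neighbour, injective, deterministic", {
  tpl <- toy_template()
  # channel exactly on a neuron coordinate maps to it
  montage <- data.frame(label = "X", x = tpl$x[5], y = tpl$y[5],
                        z = tpl$z[5])
  expect_equal(unname(map_inputs(tpl, montage)), 5L)

  # collision: lexicographically first label gets the nearest neuron
  m2 <- data.frame(label = c("B", "A"),
                   x = tpl$x[5] + c(0.1, 0.2), y = tpl$y[5], z = tpl$z[5])
  im <- map_inputs(tpl, m2)
  expect_equal(length(unique(im)), 2L)
  expect_equal(unname(im["A"]), 5L)  # "A" sorts first, takes neuron 5

  # far-away montage still maps, with a warning
  m3 <- data.frame(label = "far", x = 5000, y = 5000, z = 5000)
  expect_warning(map_inputs(tpl, m3), "away")

  big <- data.frame(label = paste0("c", seq_len(nrow(tpl) + 1)),
                    x = 0, y = 0, z = 0)
  expect_error(map_inputs(tpl, big), "more channels")
})

test_that("small-world initialisation is seeded and distance-governed", {
  tpl <- brain_template(resolution = 25)
  s1 <- init_small_world(tpl, seed = 3)
  s2 <- init_small_world(tpl, seed = 3)
  expect_identical(s1$weights, s2$weights)
  expect_false(identical(s1$weights, init_small_world(tpl, seed = 4)$weights))
  expect_true(all(diag(s1$weights) == 0))

  # no inhibitory neurons -> all weights non-negative
  s0 <- init_small_world(tpl, seed = 3, inhibitory_fraction = 0)
  expect_true(all(s0$weights >= 0))

  # realized connection rate decays with distance: compare the nearest
  # distinct grid distance against the farthest eligible one
  d <- as.matrix(dist(as.matrix(tpl[, c("x", "y", "z")])))
  r <- 0.25 * max(d)
  elig <- d > 0 & d <= r
  dv <- round(d[elig], 6)
  lev <- sort(unique(dv))
  rate_near <- mean(s1$mask[elig][dv == lev[1]])
  rate_far <- mean(s1$mask[elig][dv == lev[length(lev)]])
  expect_gt(rate_near, rate_far)

  # vanishing radius -> no synapses
  s_none <- init_small_world(tpl, seed = 3, radius_fraction = 1e-6)
  expect_equal(sum(s_none$mask), 0)
})

test_that("LIF step fires, leaks and respects the refractory period", {
  lif <- list(threshold = 0.5, tau_m = 10, refractory_ticks = 2)
  st <- step_lif(0, 0L, arriving = 0.7, dt = 0.01, lif)
  expect_true(st$fired)
  expect_equal(st$potential, 0)
  expect_equal(st$refractory, 2L)

  # two sub-threshold inputs far apart in time never reach threshold
  v <- 0
  st1 <- step_lif(v, 0L, 0.25, 0.01, lif)       # v = 0.25
  expect_false(st1$fired)
  # 5 leak-only ticks: v decays by exp(-10) ~ 0
  v <- st1$potential
  for (k in 1:5) { s <- step_lif(v, 0L, 0, 0.01, lif); v <- s$potential }
  st2 <- step_lif(v, 0L, 0.25, 0.01, lif)
  expect_false(st2$fired)
  expect_lt(st2$potential, 0.26)

  # refractory neuron ignores supra-threshold drive
  st3 <- step_lif(0, 2L, 10, 0.01, lif)
  expect_false(st3$fired)
  expect_equal(st3$potential, 0)

  # near-zero leak: fires after ceiling(threshold / w) inputs
  lif0 <- list(threshold = 0.5, tau_m = 1e9, refractory_ticks = 1)
  w <- 0.12
  v <- 0; fired_at <- NA
  for (k in 1:10) {
    s <- step_lif(v, 0L, w, 0.01, lif0)
    v <- s$potential
    if (s$fired) { fired_at <- k; break }
  }
  expect_equal(fired_at, ceiling(0.5 / w))

  expect_error(step_lif(0, 0L, 0, dt = 0, lif), "positive")
})

test_that("STDP window and total update match the closed forms and oracle", {
  p <- stdp_pars()
  expect_equal(stdp_window(20, p), 0.01 / exp(1))
  expect_equal(stdp_window(-25, p), -0.012 / exp(1))
  expect_identical(stdp_window(0, p), 0)

  # single causal pair at x = tau_plus
  expect_equal(stdp_total_update(10, 10 + 20, p), 0.01 / exp(1))
  # empty trains contribute nothing
  expect_identical(stdp_total_update(numeric(0), c(1, 2), p), 0)
  # one causal + one anti-causal pair
  expect_equal(stdp_total_update(50, c(50 + 20, 50 - 25), p),
               0.01 / exp(1) - 0.012 / exp(1))

  set.seed(99)
  for (i in 1:60) {
    pre <- sort(runif(sample(0:10, 1), 0, 200))
    post <- sort(runif(sample(0:10, 1), 0, 200))
    expect_lt(abs(stdp_total_update(pre, post, p) -
                    stdp_oracle(pre, post, p)), 1e-9)
  }

  # causal order potentiates, reversed order depresses
  pre <- c(10, 30, 50); post <- pre + 5
  expect_gt(stdp_total_update(pre, post, p), 0)
  expect_lt(stdp_total_update(post, pre, p), 0)
})

test_that("reservoir simulation relays input and learns only when enabled", {
  tpl <- toy_template()
  montage <- data.frame(label = c("a", "b"),
                        x = tpl$x[c(2, 9)], y = tpl$y[c(2, 9)],
                        z = tpl$z[c(2, 9)])
  im <- map_inputs(tpl, montage)
  syn <- init_small_world(tpl, seed = 5, w_scale = 200)
  res <- new_reservoir(tpl, syn, im,
                       lif = list(threshold = 1, tau_m = 20,
                                  refractory_ticks = 5, w_clip = c(-0.6, 0.6)))
  ras <- spike_raster(list(spike_train(seq(0.1, 0.5, by = 0.01), 1),
                           spike_train(seq(0.1, 0.5, by = 0.01), 1)),
                      labels = c("a", "b"), sample_rate = 100)

  off <- run_reservoir(res, ras, stdp = modifyList(stdp_pars(),
                                                   list(enabled = FALSE)))
  # learning disabled: weights bit-identical, raster still produced
  expect_identical(off$reservoir$weights, res$weights)
  # input neurons relay their encoder spikes 1:1
  expect_equal(off$raster$trains[[unname(im["a"])]]$times,
               ras$trains[[1]]$times)

  on1 <- run_reservoir(res, ras, stdp = stdp_pars())
  on2 <- run_reservoir(res, ras, stdp = stdp_pars())
  expect_identical(on1$reservoir$weights, on2$reservoir$weights)
  expect_false(identical(on1$reservoir$weights, res$weights))
  # clipping respected
  expect_true(all(abs(on1$reservoir$weights) <= 0.6 + 1e-12))

  bad <- spike_raster(list(spike_train(0.1, 1)), labels = "zz",
                      sample_rate = 100)
  expect_error(run_reservoir(res, bad), "input map")
})

test_that("a reliably causal two-neuron chain potentiates until the clip", {
  # two neurons, one synapse pre -> post; drive both externally so that
  # pre always fires a tick before post
  tpl <- brain_template_from_coords(
    data.frame(x = c(0, 10), y = 0, z = 0, region = c("r1", "r2")))
  syn <- list(weights = matrix(c(0, 0, 0.05, 0), 2, 2),
              mask = matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2),
              inhibitory = c(FALSE, FALSE))
  im <- c(a = 1L, b = 2L)
  res <- new_reservoir(tpl, syn, im,
                       lif = list(threshold = 1, tau_m = 20,
                                  refractory_ticks = 1, w_clip = c(-1, 1)))
  pre_t <- seq(0.1, 2.0, by = 0.1)
  ras <- spike_raster(list(spike_train(pre_t, 3),
                           spike_train(pre_t + 0.01, 3)),
                      labels = c("a", "b"), sample_rate = 100)
  w0 <- res$weights[1, 2]
  prev <- w0
  for (rep in 1:3) {
    out <- run_reservoir(res, ras, stdp = stdp_pars())
    expect_gt(out$reservoir$weights[1, 2], prev)
    prev <- out$reservoir$weights[1, 2]
    res <- out$reservoir
  }
})
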