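test_that("alpha kernel has unit peak at tau_s and a causal support", {
  expect_equal(alpha_kernel(5, 5), 1)
  expect_identical(alpha_kernel(0, 5), 0)
  expect_identical(alpha_kernel(-1, 5), 0)
  # peak location on a fine grid
  tt <- seq(0, 50, by = 0.01)
  expect_lt(abs(tt[which.max(alpha_kernel(tt, 7))] - 7), 0.02)
  expect_lte(max(alpha_kernel(tt, 7)), 1)
})

test_that("convolution superposes kernels and matches the naive oracle", {
  grid <- seq(0, 100, by = 1)
  expect_equal(convolve_train(numeric(0), 5, grid), numeric(101))
  # one spike: shifted kernel
  expect_equal(convolve_train(20, 5, grid), alpha_kernel(grid - 20, 5))

  set.seed(3)
  for (i in 1:20) {
    times <- sort(runif(sample(1:20, 1), 0, 100))
    tau_s <- runif(1, 2, 20)
    naive <- sapply(grid, function(tt)
      sum(sapply(times, function(tf)
        if (tt >= tf) exp(1) * (tt - tf) / tau_s * exp(-(tt - tf) / tau_s)
        else 0)))
    expect_lt(max(abs(convolve_train(times, tau_s, grid) - naive)), 1e-9)
  }
})

test_that("synaptic current is the weighted superposition of afferents", {
  grid <- seq(0, 50, by = 1)
  t1 <- c(5, 20); t2 <- c(10, 30)
  expect_equal(span_current(list(t1), 1, 5, grid),
               convolve_train(t1, 5, grid))
  expect_equal(span_current(list(t1, t2), c(0, 0), 5, grid), numeric(51))
  expect_equal(span_current(list(t1, t2), c(2, -1), 5, grid),
               2 * convolve_train(t1, 5, grid) - convolve_train(t2, 5, grid))
  expect_error(span_current(list(t1, t2), 1, 5, grid), "one weight")
})

test_that("firing emits one spike per threshold crossing", {
  grid <- seq(0, 100, by = 1)
  cur <- convolve_train(10, 5, grid)   # peak 1 at t = 15
  expect_equal(span_fire(cur, 1.5, grid), numeric(0))
  # peak value exactly at threshold: single spike at t0 + tau_s
  expect_equal(span_fire(cur, 1, grid), 15)
  # sustained supra-threshold current yields a single crossing spike
  expect_equal(span_fire(rep(2, 50), 1, seq_len(50)), 1)
  # raw mode spikes on every supra-threshold grid point
  expect_equal(length(span_fire(rep(2, 50), 1, seq_len(50),
                                hysteresis = FALSE)), 50)
})

test_that("delta rule reproduces the worked value and its symmetries", {
  # single input at 5, desired at 10, no output, lambda 1, tau 5
  expect_equal(span_delta_update(list(5), 10, numeric(0), 1, 5), 0.4)

  # pure depression when nothing is desired
  expect_lt(span_delta_update(list(c(5, 10)), numeric(0), c(7, 12), 1, 5), 0)

  set.seed(21)
  for (i in 1:40) {
    ti <- sort(runif(sample(1:8, 1), 0, 100))
    td <- sort(runif(sample(1:8, 1), 0, 100))
    to <- sort(runif(sample(0:8, 1), 0, 100))
    # fixed point: identical desired and actual trains cancel exactly
    expect_identical(span_delta_update(list(ti), td, td, 1, 7), 0)
    # exchanging desired and actual flips the sign
    expect_equal(span_delta_update(list(ti), td, to, 1, 7),
                 -span_delta_update(list(ti), to, td, 1, 7))
  }

  # brute-force oracle on the full expression
  oracle <- function(ti, td, to, lam, tau) {
    term <- function(a, b) {
      s <- 0
      for (x in a) for (y in b)
        s <- s + (abs(x - y) + tau) * exp(-abs(x - y) / tau)
      s
    }
    lam * exp(1) / tau^2 * (term(ti, td) - term(ti, to))
  }
  set.seed(22)
  for (i in 1:20) {
    ti <- sort(runif(5, 0, 50)); td <- sort(runif(3, 0, 50))
    to <- sort(runif(4, 0, 50))
    expect_lt(abs(span_delta_update(list(ti), td, to, 0.3, 9) -
                    oracle(ti, td, to, 0.3, 9)), 1e-9)
  }
})

test_that("training stops immediately at the exact-match fixed point", {
  cfg <- snn_control()$span
  grid <- seq(0, 500, by = 10)
  # weights already produce the desired spike: current peak 1 at 110 + tau_s
  ti <- 110
  cur <- convolve_train(ti, cfg$tau_s, grid)
  desired <- grid[which.max(cur)]
  fit <- train_span(list(ti), desired, grid, cfg,
                    init_weights = cfg$th_m / max(cur))
  expect_true(fit$trained)
  expect_equal(fit$epochs, 1L)
  expect_equal(fit$weights, cfg$th_m / max(cur))  # untouched
})

test_that("training cannot converge without afferent spikes", {
  cfg <- snn_control()$span
  cfg$max_epochs <- 10
  fit <- train_span(list(numeric(0)), 100, seq(0, 500, by = 10), cfg)
  expect_false(fit$trained)
  expect_equal(fit$output, numeric(0))
  expect_equal(length(fit$trace), 10)
})

test_that("median training error is non-increasing early on", {
  cfg <- snn_control()$span
  cfg$max_epochs <- 10
  grid <- seq(0, 500, by = 5)
  traces <- sapply(1:12, function(s) {
    set.seed(s)
    ti <- sort(runif(rpois(1, 5) + 1, 0, 500))
    fit <- train_span(list(ti), 250, grid, cfg)
    length(fit$trace) <- 10
    fit$trace
  })
  med <- apply(traces, 1, stats::median, na.rm = TRUE)
  # overall downward trend across the first epochs
  expect_lte(min(med, na.rm = TRUE), med[1])
  expect_lte(med[10], med[1])
})
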