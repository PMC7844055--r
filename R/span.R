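#' Alpha kernel for spike convolution
#'
#' `alpha(t) = e * t / tau_s * exp(-t / tau_s)` for `t >= 0` and 0 for
#' `t < 0` (Heaviside gate). The kernel rises from 0, peaks at exactly 1
#' when `t = tau_s`, and decays exponentially; it is what turns a discrete
#' spike train into the continuous trace the SPAN layer and the evaluation
#' use.
#'
#' @param t time since the spike; vectorised. Any time unit, as long as it
#'   matches `tau_s`.
#' @param tau_s synaptic time constant (> 0).
#' @return Numeric vector of kernel values.
#' @export
#' @examples
#' alpha_kernel(c(-1, 0, 5), tau_s = 5)  # 0, 0, 1
alpha_kernel <- function(t, tau_s) {
  stopifnot(tau_s > 0)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- exp(1) * t[pos] / tau_s * exp(-t[pos] / tau_s)
  out
}

#' Convolve a spike train with the alpha kernel
#'
#' Superposition over all spikes: `s(t) = sum_f alpha(t - t_f)` evaluated on
#' a time grid. Direct summation; exact, used for scoring and as the oracle
#' partner of the streaming recursive filter.
#'
#' @param train a [spike_train()] or numeric vector of spike times.
#' @param tau_s kernel time constant, same unit as the grid.
#' @param grid numeric vector of evaluation times.
#' @return Numeric vector, one amplitude per grid point.
#' @export
convolve_train <- function(train, tau_s, grid) {
  times <- if (inherits(train, "spike_train")) train$times else train
  if (!length(times)) return(numeric(length(grid)))
  s <- numeric(length(grid))
  for (tf in times) s <- s + alpha_kernel(grid - tf, tau_s)
  s
}

# Recursive alpha-kernel filter on a uniform grid. Exact for tick-aligned
# spikes: maintains A(t) = sum exp(-(t - t_f)/tau_s) and
# B(t) = sum (t - t_f) exp(-(t - t_f)/tau_s), so s = e/tau_s * B. The state
# can be carried across chunks, which is what makes streaming prediction
# bit-identical to batch prediction (same recursion either way).
# spike_counts: integer vector, spikes landing on each tick of the chunk.
alpha_filter_chunk <- function(spike_counts, dt, tau_s,
                               state = c(A = 0, B = 0)) {
  rho <- exp(-dt / tau_s)
  K <- length(spike_counts)
  s <- numeric(K)
  A <- state[["A"]]; B <- state[["B"]]
  for (k in seq_len(K)) {
    B <- rho * (B + dt * A)
    A <- rho * A + spike_counts[k]
    s[k] <- B
  }
  list(values = exp(1) / tau_s * s, state = c(A = A, B = B))
}

#' Synaptic current of a SPAN neuron
#'
#' Weighted superposition of the alpha-convolved afferent trains:
#' `I(t) = sum_i w_i * sum_f alpha(t - t_i^f)`.
#'
#' @param afferents list of spike-time vectors (or [spike_train()]s), one
#'   per afferent.
#' @param weights numeric vector, one weight per afferent.
#' @param tau_s kernel time constant, same unit as `grid`.
#' @param grid evaluation time grid.
#' @return Numeric vector of current values on the grid.
#' @export
span_current <- function(afferents, weights, tau_s, grid) {
  if (length(afferents) != length(weights))
    stop("one weight per afferent required", call. = FALSE)
  cur <- numeric(length(grid))
  for (i in seq_along(afferents))
    if (weights[i] != 0)
      cur <- cur + weights[i] * convolve_train(afferents[[i]], tau_s, grid)
  cur
}

#' Threshold firing of a SPAN neuron
#'
#' Emits spikes where the synaptic current reaches the firing threshold.
#' By default one spike is emitted per upward threshold crossing and
#' further spikes are suppressed until the current falls back below
#' threshold (fire-and-reset hysteresis), so a sustained supra-threshold
#' current yields a single spike rather than a burst. The raw mode
#' (`hysteresis = FALSE`) spikes at every supra-threshold grid point and
#' exists for oracle comparisons.
#'
#' @param current numeric vector of current values on the grid.
#' @param th_m firing threshold.
#' @param grid evaluation time grid (same length as `current`).
#' @param hysteresis suppress repeats until the current drops below
#'   threshold?
#' @return Numeric vector of spike times (subset of `grid`).
#' @export
span_fire <- function(current, th_m, grid, hysteresis = TRUE) {
  stopifnot(length(current) == length(grid))
  above <- current >= th_m
  if (!hysteresis) return(grid[above])
  crossing <- above & !c(FALSE, above[-length(above)])
  grid[crossing]
}

#' SPAN delta-rule weight update
#'
#' The spike-domain Widrow-Hoff rule: for afferent `i`,
#' `dw_i = lambda * (e / tau^2) * (sum over (input, desired) spike pairs of
#' (|dt| + tau) exp(-|dt| / tau)  -  the same sum over (input, actual)
#' pairs)`. Input spikes near desired times potentiate; input spikes near
#' actual (emitted) times depress; when the actual train equals the desired
#' train the two sums cancel term by term and the update is exactly zero.
#'
#' @param t_input list of spike-time vectors, one per afferent (or a single
#'   numeric vector for one afferent).
#' @param t_desired numeric vector of desired output spike times.
#' @param t_actual numeric vector of actually emitted spike times.
#' @param lambda learning rate.
#' @param tau learning-kernel time constant, same unit as the spike times.
#' @return Numeric vector of weight updates, one per afferent.
#' @export
#' @examples
#' span_delta_update(list(5), t_desired = 10, t_actual = numeric(0),
#'                   lambda = 1, tau = 5)  # 0.4
span_delta_update <- function(t_input, t_desired, t_actual, lambda, tau) {
  stopifnot(lambda > 0, tau > 0)
  if (!is.list(t_input)) t_input <- list(t_input)
  pair_sum <- function(a, b) {
    if (!length(a) || !length(b)) return(0)
    ad <- abs(outer(a, b, `-`))
    sum((ad + tau) * exp(-ad / tau))
  }
  vapply(t_input, function(ti)
    lambda * exp(1) / tau^2 *
      (pair_sum(ti, t_desired) - pair_sum(ti, t_actual)),
    numeric(1))
}

# sorted-sequence spike-train match: equal counts and every desired spike
# paired with an actual spike within +/- tol, no unmatched spikes either side
spikes_match <- function(desired, actual, tol) {
  if (length(desired) != length(actual)) return(FALSE)
  if (!length(desired)) return(TRUE)
  all(abs(sort(desired) - sort(actual)) <= tol)
}

#' Train a SPAN neuron to emit a desired spike train
#'
#' Iterates current computation, thresholded firing and the delta-rule
#' update over all afferent weights for up to `max_epochs` epochs, stopping
#' early when the emitted train matches the desired train within the match
#' tolerance (equal spike counts and every desired spike paired with an
#' emitted spike within the tolerance). Non-convergence is not an error:
#' the neuron is returned with `trained = FALSE` and the full error trace.
#'
#' The raw delta-rule step grows with the number of spike pairs, so on
#' dense trains it can overshoot by orders of magnitude. Each epoch's
#' update therefore keeps the delta-rule direction but is rescaled when its
#' largest component exceeds `step_cap` (a trust-region on the epoch step);
#' the exact-match fixed point is unaffected since a zero update stays
#' zero.
#'
#' @param afferents list of spike-time vectors, one per afferent.
#' @param desired numeric vector of desired output spike times.
#' @param grid uniform evaluation time grid covering the observation window.
#' @param config list with `tau_s`, `lambda`, `tau`, `th_m`, `max_epochs`,
#'   `match_tolerance` and optional `step_cap` (see [snn_control()]; times
#'   in the grid's unit).
#' @param init_weights optional initial weights; defaults to small positive
#'   uniform draws from the current RNG state.
#' @param S optional precomputed afferent convolution matrix
#'   (`length(grid)` x `length(afferents)`), to avoid reconvolving when the
#'   caller already has it.
#' @return List with `weights`, `trained` (logical), `output` (spike times
#'   at the final weights), `epochs` used, and `trace` (per-epoch
#'   van-Rossum-style L2 distance between desired and emitted convolved
#'   trains).
#' @export
train_span <- function(afferents, desired, grid, config,
                       init_weights = NULL, S = NULL) {
  stopifnot(is.list(afferents), length(afferents) >= 1)
  n_aff <- length(afferents)
  if (is.null(init_weights))
    init_weights <- stats::runif(n_aff, 0, 0.1)
  w <- init_weights
  dt <- if (length(grid) > 1) grid[2] - grid[1] else 1
  # afferent convolutions are fixed across epochs
  if (is.null(S))
    S <- vapply(afferents, function(ti) convolve_train(ti, config$tau_s, grid),
                numeric(length(grid)))
  conv_desired <- convolve_train(desired, config$tau_s, grid)
  target_term <- vapply(afferents, function(ti)
    if (!length(ti) || !length(desired)) 0 else {
      ad <- abs(outer(ti, desired, `-`))
      sum((ad + config$tau) * exp(-ad / config$tau))
    }, numeric(1))

  trace <- numeric(0)
  trained <- FALSE
  output <- numeric(0)
  epochs <- 0L
  for (ep in seq_len(config$max_epochs)) {
    epochs <- ep
    current <- as.numeric(S %*% w)
    output <- span_fire(current, config$th_m, grid)
    conv_out <- convolve_train(output, config$tau_s, grid)
    trace <- c(trace, sqrt(sum((conv_desired - conv_out)^2) * dt))
    if (spikes_match(desired, output, config$match_tolerance)) {
      trained <- TRUE
      break
    }
    out_term <- vapply(afferents, function(ti)
      if (!length(ti) || !length(output)) 0 else {
        ad <- abs(outer(ti, output, `-`))
        sum((ad + config$tau) * exp(-ad / config$tau))
      }, numeric(1))
    dw <- config$lambda * exp(1) / config$tau^2 * (target_term - out_term)
    cap <- config$step_cap %||% Inf
    peak <- max(abs(dw))
    if (is.finite(cap) && peak > cap) dw <- dw * (cap / peak)
    w <- w + dw
  }
  list(weights = w, trained = trained, output = output, epochs = epochs,
       trace = trace)
}
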