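#' Small-world initialisation of the reservoir synapses
#'
#' Creates directed synapses between template neurons following the
#' small-world principle: only pairs closer than a radius `r =
#' radius_fraction * max pairwise distance` may connect, and within that
#' radius the connection probability decays exponentially with distance,
#' `p(d) = p0 * exp(-d / lambda_d)`, yielding dense local and sparse
#' longer-range links. Weight magnitudes are drawn `Uniform(0, w_scale) / d`
#' so nearby synapses are on average stronger. A seeded subset of
#' presynaptic neurons (`inhibitory_fraction`) emits negative weights on all
#' outgoing synapses. No self-connections.
#'
#' @param template a [brain_template()].
#' @param seed integer seed; the synapse set is a deterministic function of
#'   `(template, seed, parameters)`.
#' @param radius_fraction small-world radius as a fraction of the maximum
#'   pairwise distance, in `(0, 1]`.
#' @param p0,lambda_d connection-probability parameters; `lambda_d = NULL`
#'   defaults to half the small-world radius.
#' @param inhibitory_fraction fraction of neurons whose outgoing weights are
#'   negative.
#' @param w_scale weight magnitude scale; `NULL` defaults to five times the
#'   template grid resolution. With the default LIF weight bounds this puts
#'   most local synapses at the bound, so distance shapes the network mainly
#'   through connection probability.
#'
#' @return A list with dense numeric `weights` (n x n, entry `[i, j]` is the
#'   synapse i -> j, 0 where absent), logical `mask` of existing synapses,
#'   and the logical `inhibitory` vector.
#' @export
init_small_world <- function(template, seed, radius_fraction = 0.25,
                             p0 = 0.8, lambda_d = NULL,
                             inhibitory_fraction = 0.2, w_scale = NULL) {
  stopifnot(inherits(template, "brain_template"),
            radius_fraction > 0, radius_fraction <= 1,
            inhibitory_fraction >= 0, inhibitory_fraction <= 1)
  coords <- as.matrix(template[, c("x", "y", "z")])
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  r <- radius_fraction * max(d)
  if (is.null(lambda_d)) lambda_d <- r / 2
  if (is.null(w_scale)) {
    res <- attr(template, "resolution")
    w_scale <- if (is.null(res)) 2 * r else 5 * res
  }
  set.seed(seed)
  p <- p0 * exp(-d / lambda_d)
  elig <- d <= r & d > 0
  conn <- elig & matrix(stats::runif(n * n), n, n) < p
  w <- matrix(0, n, n)
  if (any(conn))
    w[conn] <- stats::runif(sum(conn), 0, w_scale) / d[conn]
  inhib <- rep(FALSE, n)
  n_inh <- floor(inhibitory_fraction * n)
  if (n_inh > 0) inhib[sample.int(n, n_inh)] <- TRUE
  w[inhib, ] <- -w[inhib, ]
  list(weights = w, mask = conn, inhibitory = inhib)
}

#' Assemble a spiking reservoir
#'
#' Binds a template, an input mapping and an initial synapse set together
#' with the leaky integrate-and-fire (LIF) parameters into a reservoir
#' object ready for simulation. Input-mapped neurons act as relays: each
#' encoder spike on a channel makes its neuron fire deterministically at
#' that tick, so input drive is not attenuated by the leak.
#'
#' @param template a [brain_template()].
#' @param synapses result of [init_small_world()].
#' @param input_map named integer vector from [map_inputs()].
#' @param lif list with `threshold`, `tau_m` (membrane time constant, ms),
#'   `refractory_ticks`, `w_clip` (length-2 weight bounds).
#' @return An object of class `snn_reservoir`.
#' @export
new_reservoir <- function(template, synapses, input_map,
                          lif = list(threshold = 0.5, tau_m = 10,
                                     refractory_ticks = 1,
                                     w_clip = c(-1, 1))) {
  stopifnot(inherits(template, "brain_template"))
  n <- nrow(template)
  if (any(diag(synapses$weights) != 0)) stop("self-synapses present",
                                             call. = FALSE)
  if (anyDuplicated(input_map)) stop("input_map must be injective",
                                     call. = FALSE)
  if (any(input_map < 1 | input_map > n)) stop("input_map out of range",
                                               call. = FALSE)
  if (!all(is.finite(synapses$weights))) stop("non-finite weights",
                                              call. = FALSE)
  clip <- lif$w_clip %||% c(-1, 1)
  synapses$weights <- pmin(pmax(synapses$weights, clip[1]), clip[2])
  structure(list(template = template, weights = synapses$weights,
                 mask = synapses$mask, inhibitory = synapses$inhibitory,
                 input_map = input_map, lif = lif),
            class = "snn_reservoir")
}

#' @export
print.snn_reservoir <- function(x, ...) {
  cat(sprintf("<snn_reservoir> %d neurons, %d synapses, %d input channels\n",
              nrow(x$template), sum(x$mask), length(x$input_map)))
  invisible(x)
}

#' One tick of leaky integrate-and-fire dynamics
#'
#' Pure state-update step: membrane potentials decay exponentially with the
#' leak time constant, arriving synaptic input is added, neurons at or above
#' threshold fire and reset to 0, and refractory neurons are held silent
#' with their potential clamped to 0.
#'
#' @param potential numeric vector of membrane potentials.
#' @param refractory integer vector of remaining refractory ticks.
#' @param arriving numeric vector of summed synaptic input arriving this
#'   tick.
#' @param dt tick length in seconds (> 0).
#' @param lif list with `threshold`, `tau_m` (ms), `refractory_ticks`.
#' @return List with updated `potential`, `refractory` and logical `fired`.
#' @export
#' @examples
#' st <- step_lif(0, 0L, arriving = 0.7, dt = 0.01,
#'                lif = list(threshold = 0.5, tau_m = 10, refractory_ticks = 1))
#' st$fired
step_lif <- function(potential, refractory, arriving, dt, lif) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  decay <- exp(-dt * 1000 / lif$tau_m)
  v <- potential * decay + arriving
  blocked <- refractory > 0
  v[blocked] <- 0
  fired <- !blocked & v >= lif$threshold
  v[fired] <- 0
  refractory <- pmax(refractory - 1L, 0L)
  refractory[fired] <- as.integer(lif$refractory_ticks)
  list(potential = v, refractory = refractory, fired = fired)
}

#' STDP learning window
#'
#' Exponential spike-timing-dependent plasticity window: potentiation
#' `A_plus * exp(-x / tau_plus)` for a causal pre-before-post interval
#' `x > 0`, depression `-A_minus * exp(x / tau_minus)` for `x < 0`, and 0 at
#' `x = 0` (simultaneous spikes produce no update; the window is otherwise
#' undefined there).
#'
#' @param x time difference (post minus pre) in the same units as the time
#'   constants; vectorised.
#' @param params list with `A_plus`, `A_minus`, `tau_plus`, `tau_minus`.
#' @return Numeric vector of weight updates.
#' @export
#' @examples
#' stdp_window(20, list(A_plus = 0.01, A_minus = 0.01,
#'                      tau_plus = 20, tau_minus = 20))  # A_plus / e
stdp_window <- function(x, params) {
  stopifnot(params$A_plus > 0, params$A_minus > 0,
            params$tau_plus > 0, params$tau_minus > 0)
  out <- numeric(length(x))
  pos <- is.finite(x) & x > 0
  neg <- is.finite(x) & x < 0
  out[pos] <- params$A_plus * exp(-x[pos] / params$tau_plus)
  out[neg] <- -params$A_minus * exp(x[neg] / params$tau_minus)
  out
}

#' Total STDP update over two spike trains
#'
#' The all-pairs form: `sum_f sum_n W(t_post^n - t_pre^f)` over every
#' pre/post spike pair. This is the offline/oracle form; the online
#' simulation applies the window to nearest spikes only at fire events.
#'
#' @param pre,post numeric vectors of spike times (or [spike_train()]
#'   objects), in the same units as the window time constants.
#' @param params see [stdp_window()].
#' @return Single numeric weight update.
#' @export
stdp_total_update <- function(pre, post, params) {
  if (inherits(pre, "spike_train")) pre <- pre$times
  if (inherits(post, "spike_train")) post <- post$times
  if (!length(pre) || !length(post)) return(0)
  sum(stdp_window(outer(post, pre, `-`), params))
}

#' Simulate the reservoir over an input raster, with optional plasticity
#'
#' Drives the reservoir tick by tick on the input raster's sample grid.
#' Input-mapped neurons relay encoder spikes 1:1; all other neurons follow
#' LIF dynamics on the synaptic input from spikes emitted at the previous
#' tick (one-tick synaptic delay). When learning is enabled the modified,
#' fire-triggered STDP rule is applied: weights change only when a neuron
#' fires (never on mere spike receipt), and a fire event at time `t` updates
#' both sides of the firing neuron `j` - every incoming synapse `i -> j`
#' gains `W(t - last_spike_i)` (potentiation when `i` fired before `j`) and
#' every outgoing synapse `j -> k` gains `W(last_spike_k - t)` (depression
#' when `k` has not fired since). Nearest spikes only; simultaneous fires
#' give no update; weights are clipped to the configured bounds.
#'
#' @param reservoir a [new_reservoir()] object.
#' @param input_raster a [spike_raster()] whose labels are all present in
#'   the reservoir's input map and which carries a sample rate.
#' @param stdp list with `A_plus`, `A_minus`, `tau_plus`, `tau_minus` (ms)
#'   and `enabled`.
#' @param n_ticks number of ticks to simulate; defaults to the raster
#'   duration.
#' @return List with the updated `reservoir` (trained weights), the
#'   reservoir `raster` (a [spike_raster()] over all neurons) and
#'   `spike_ticks` (list of integer tick indices per neuron, 1-based).
#' @export
run_reservoir <- function(reservoir, input_raster,
                          stdp = list(A_plus = 0.01, A_minus = 0.01,
                                      tau_plus = 20, tau_minus = 20,
                                      enabled = TRUE),
                          n_ticks = NULL) {
  stopifnot(inherits(reservoir, "snn_reservoir"),
            inherits(input_raster, "spike_raster"))
  sr <- input_raster$sample_rate
  if (is.null(sr)) stop("input raster needs a sample rate", call. = FALSE)
  if (!all(input_raster$labels %in% names(reservoir$input_map)))
    stop("raster channel absent from input map", call. = FALSE)
  dt <- 1 / sr
  if (is.null(n_ticks))
    n_ticks <- as.integer(round(input_raster$duration * sr)) + 1L
  n <- nrow(reservoir$template)

  # input spikes as a tick-indexed list per mapped neuron
  input_at <- vector("list", n_ticks)
  for (lb in input_raster$labels) {
    neuron <- reservoir$input_map[[lb]]
    ticks <- round(input_raster$trains[[lb]]$times * sr) + 1L
    ticks <- ticks[ticks >= 1 & ticks <= n_ticks]
    for (k in ticks) input_at[[k]] <- c(input_at[[k]], neuron)
  }
  input_neurons <- unname(reservoir$input_map)
  is_input <- rep(FALSE, n); is_input[input_neurons] <- TRUE

  w <- reservoir$weights
  mask <- reservoir$mask
  lif <- reservoir$lif
  clip <- lif$w_clip %||% c(-1, 1)
  learn <- isTRUE(stdp$enabled)

  v <- numeric(n)
  refrac <- integer(n)
  last_spike <- rep(-Inf, n)
  fired_prev <- logical(n)
  spikes <- vector("list", n)
  counts <- integer(n)
  spike_store <- lapply(seq_len(n), function(i) integer(0))

  for (k in seq_len(n_ticks)) {
    t_now <- (k - 1) * dt
    arriving <- if (any(fired_prev)) {
      if (sum(fired_prev) == 1L) w[, which(fired_prev)]
      else rowSums(w[, fired_prev, drop = FALSE])
    } else numeric(n)
    st <- step_lif(v, refrac, arriving, dt, lif)
    fired <- st$fired & !is_input
    # relay: input neurons fire exactly on encoder spikes
    inp <- input_at[[k]]
    if (!is.null(inp)) fired[inp] <- TRUE
    v <- st$potential
    refrac <- st$refractory
    v[is_input] <- 0

    if (learn && any(fired)) {
      last2 <- last_spike
      last2[fired] <- t_now
      # ms-domain intervals; stdp_window(0) == 0 covers simultaneous fires
      d_in <- stdp_window((t_now - last2) * 1000, stdp)
      d_out <- stdp_window((last2 - t_now) * 1000, stdp)
      fcols <- which(fired)
      w[, fcols] <- w[, fcols] + d_in * mask[, fcols, drop = FALSE]
      w[fcols, ] <- w[fcols, , drop = FALSE] +
        mask[fcols, , drop = FALSE] * rep(d_out, each = length(fcols))
      if (any(w < clip[1]) || any(w > clip[2]))
        w <- pmin(pmax(w, clip[1]), clip[2])
    }

    if (any(fired)) {
      fidx <- which(fired)
      for (i in fidx) spike_store[[i]] <- c(spike_store[[i]], k)
      last_spike[fidx] <- t_now
      v[fidx] <- 0
      refrac[fidx] <- as.integer(lif$refractory_ticks)
    }
    fired_prev <- fired
  }

  duration <- (n_ticks - 1) * dt
  trains <- lapply(spike_store, function(ticks)
    spike_train((ticks - 1) * dt, duration))
  raster <- spike_raster(trains, labels = paste0("n", seq_len(n)),
                         sample_rate = sr)
  reservoir$weights <- w
  list(reservoir = reservoir, raster = raster, spike_ticks = spike_store)
}

#' Partition reservoir neurons into anatomical clusters
#'
#' @param x a [new_reservoir()] or [brain_template()].
#' @return Named list (sorted region labels) of integer neuron index
#'   vectors; the clusters partition the reservoir and none is empty.
#' @export
extract_clusters <- function(x) {
  template <- if (inherits(x, "snn_reservoir")) x$template else x
  stopifnot(inherits(template, "brain_template"))
  labs <- sort(unique(template$region))
  out <- lapply(labs, function(lb) which(template$region == lb))
  names(out) <- labs
  out
}
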