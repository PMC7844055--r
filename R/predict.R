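#' Predict target signals from new input, batch or pseudo-online
#'
#' Runs the fitted pipeline over a new input signal: incremental threshold
#' encoding, frozen-weight reservoir dynamics (no plasticity), member SPAN
#' currents and firing, readout population states, and threshold-based
#' decoding back to continuous target signals. The engine is a stateful
#' tick loop; `mode = "batch"` feeds the whole signal through it in one
#' chunk while `mode = "streaming"` feeds one tick at a time (pseudo-online
#' replay), so the two modes produce identical spike trains, states and
#' decoded signals by construction, and streaming additionally logs
#' per-tick wall-clock latency.
#'
#' @param object a fitted [snn_decoder()].
#' @param newdata a [continuous_signal()] whose channels match the training
#'   montage.
#' @param events optional data.frame of test trial `start` (and optionally
#'   `onset`, `end`) times; when given, decoding re-anchors each trial at
#'   the target's initial value and signed (kinematics) targets use their
#'   learned per-slot sign profile. Without it all targets are decoded with
#'   all-positive steps from the session start.
#' @param mode `"batch"` or `"streaming"`.
#' @param ... unused.
#' @return An object of class `snn_prediction`: list with `q` (tick x
#'   population binary readout states), `currents` (readout currents),
#'   `member_spikes` (per population, per member spike times in seconds),
#'   `readout_spikes` (per population), `decoded` (a [continuous_signal()]
#'   over the target channels), `latency` (per-tick seconds; streaming
#'   mode), `mode` and `sample_rate`.
#' @export
predict.snn_decoder <- function(object, newdata, events = NULL,
                                mode = c("batch", "streaming"), ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(newdata, "continuous_signal"))
  if (!all(newdata$channel_labels %in% names(object$input_map)))
    stop("input channels do not match the training montage", call. = FALSE)
  K <- nrow(newdata$values)
  chunks <- if (mode == "streaming") as.list(seq_len(K)) else list(seq_len(K))

  st <- engine_init(object, newdata$channel_labels)
  out <- engine_alloc(object, K)
  latency <- if (mode == "streaming") numeric(K) else numeric(0)
  for (ch in chunks) {
    if (mode == "streaming") t0 <- proc.time()[["elapsed"]]
    st <- engine_run(object, st, newdata$values[ch, , drop = FALSE], out, ch)
    if (mode == "streaming")
      latency[ch] <- proc.time()[["elapsed"]] - t0
  }

  sr <- object$sample_rate
  pops <- names(object$populations)
  q <- out$q
  colnames(q) <- pops
  currents <- out$currents
  colnames(currents) <- pops
  member_spikes <- lapply(pops, function(lb) {
    lapply(out$member_ticks[[lb]], function(tk) (tk - 1) / sr)
  })
  names(member_spikes) <- pops
  readout_spikes <- lapply(pops, function(lb) (which(q[, lb] == 1) - 1) / sr)
  names(readout_spikes) <- pops

  decoded <- decode_prediction(object, readout_spikes, K, events)

  structure(list(q = q, currents = currents, member_spikes = member_spikes,
                 readout_spikes = readout_spikes, decoded = decoded,
                 latency = latency, mode = mode, sample_rate = sr,
                 n_ticks = K),
            class = "snn_prediction")
}

#' @export
print.snn_prediction <- function(x, ...) {
  cat(sprintf("<snn_prediction> %d ticks (%s mode), %d populations\n",
              x$n_ticks, x$mode, ncol(x$q)))
  act <- colMeans(x$q)
  cat("  readout active fraction:",
      paste(sprintf("%s %.2f", colnames(x$q), act), collapse = ", "), "\n")
  invisible(x)
}

# ---- engine internals -------------------------------------------------

# mutable state for the tick loop
engine_init <- function(model, channel_labels) {
  n <- nrow(model$reservoir$template)
  pops <- model$populations
  n_members <- vapply(pops, function(p) length(p$members), integer(1))
  total_m <- sum(n_members)
  # member weight matrix (total members x neurons), afferent-sparse
  Wm <- matrix(0, total_m, n)
  row <- 0L
  for (p in pops) for (m in p$members) {
    row <- row + 1L
    Wm[row, m$afferents] <- m$weights
  }
  list(
    prev_sample = NULL,          # last input sample seen (per channel)
    v = numeric(n), refrac = integer(n), fired_prev = logical(n),
    A = numeric(n), B = numeric(n),          # neuron alpha-filter states
    above = logical(total_m),                # member hysteresis flags
    A2 = numeric(total_m), B2 = numeric(total_m),  # member output filters
    Wm = Wm, n_members = n_members,
    tick = 0L,
    channel_labels = channel_labels
  )
}

engine_alloc <- function(model, K) {
  pops <- names(model$populations)
  out <- new.env(parent = emptyenv())
  out$q <- matrix(0L, K, length(pops))
  out$currents <- matrix(0, K, length(pops))
  out$member_ticks <- lapply(model$populations, function(p)
    lapply(p$members, function(m) integer(0)))
  names(out$member_ticks) <- pops
  out
}

# process a chunk of samples (rows), updating state and writing outputs
engine_run <- function(model, st, samples, out, tick_idx) {
  sr <- model$sample_rate
  dt <- 1 / sr
  dt_ms <- 1000 / sr
  lif <- model$reservoir$lif
  w <- model$reservoir$weights
  tau_s <- model$control$span$tau_s
  rho <- exp(-dt_ms / tau_s)
  th_m <- model$control$span$th_m
  n <- length(st$v)
  labels <- st$channel_labels
  th_in <- model$thresholds_in$channels
  input_neurons <- model$input_map[labels]
  pops <- model$populations
  pop_names <- names(pops)
  mem_of_pop <- split(seq_len(sum(st$n_members)),
                      rep(seq_along(st$n_members), st$n_members))
  w_readout <- unlist(lapply(pops, function(p)
    vapply(p$members, function(m) m$w_readout %||% 1, numeric(1))),
    use.names = FALSE)
  if (is.null(w_readout)) w_readout <- numeric(0)

  for (r in seq_len(nrow(samples))) {
    k <- tick_idx[r]
    x <- samples[r, ]
    # incremental threshold encoding against the previous sample
    fired_in <- integer(0)
    if (!is.null(st$prev_sample)) {
      dx <- x - st$prev_sample
      hit <- vapply(seq_along(labels), function(j) {
        th <- th_in[[labels[j]]]$th
        th > 0 && abs(dx[j]) >= th
      }, logical(1))
      fired_in <- input_neurons[hit]
    }
    st$prev_sample <- x

    arriving <- if (any(st$fired_prev)) {
      if (sum(st$fired_prev) == 1L) w[, which(st$fired_prev)]
      else rowSums(w[, st$fired_prev, drop = FALSE])
    } else numeric(n)
    lst <- step_lif(st$v, st$refrac, arriving, dt, lif)
    fired <- lst$fired
    is_input <- rep(FALSE, n); is_input[input_neurons] <- TRUE
    fired[is_input] <- FALSE
    if (length(fired_in)) fired[fired_in] <- TRUE
    st$v <- lst$potential
    st$refrac <- lst$refractory
    st$v[is_input] <- 0
    if (any(fired)) {
      st$v[fired] <- 0
      st$refrac[fired] <- as.integer(lif$refractory_ticks)
    }
    st$fired_prev <- fired

    # neuron alpha filters (reservoir spike convolution)
    st$B <- rho * (st$B + dt_ms * st$A)
    st$A <- rho * st$A + as.numeric(fired)
    s_tilde <- exp(1) / tau_s * st$B

    # member currents and hysteretic firing
    if (nrow(st$Wm)) {
      cur_m <- as.numeric(st$Wm %*% s_tilde)
      above_now <- cur_m >= th_m
      spike_m <- above_now & !st$above
      st$above <- above_now
      # member output alpha filters
      st$B2 <- rho * (st$B2 + dt_ms * st$A2)
      st$A2 <- rho * st$A2 + as.numeric(spike_m)
      s_members <- exp(1) / tau_s * st$B2
      if (any(spike_m)) {
        idx <- which(spike_m)
        row0 <- 0L
        for (pi in seq_along(pop_names)) {
          nm <- st$n_members[pi]
          sel <- idx[idx > row0 & idx <= row0 + nm] - row0
          for (mi in sel)
            out$member_ticks[[pop_names[pi]]][[mi]] <-
              c(out$member_ticks[[pop_names[pi]]][[mi]], k)
          row0 <- row0 + nm
        }
      }
      # population readout currents (normalised by training scale)
      for (pi in seq_along(pop_names)) {
        rows <- mem_of_pop[[pi]]
        if (is.null(rows) || !length(rows)) next
        pc <- sum(w_readout[rows] * s_members[rows]) / length(rows)
        pc <- pc / pops[[pi]]$current_scale
        out$currents[k, pi] <- pc
        out$q[k, pi] <- as.integer(pc >= pops[[pi]]$th_n)
      }
    }
    st$tick <- k
  }
  st
}

# decode readout spike trains into continuous target signals
decode_prediction <- function(model, readout_spikes, K, events) {
  sr <- model$sample_rate
  duration <- (K - 1) / sr
  labels <- model$target_labels
  trains <- vector("list", length(labels))
  policies <- character(length(labels))
  for (j in seq_along(labels)) {
    lb <- labels[j]
    times <- readout_spikes[[lb]]
    kind <- model$target_kind[[lb]]
    if (kind == "kin" && !is.null(events) && !is.null(model$sign_profiles[[lb]])) {
      prof <- model$sign_profiles[[lb]]
      signs <- vapply(times, function(tt) {
        prior <- events$start[events$start <= tt]
        if (!length(prior)) return(0L)  # outside any trial: no step
        slot <- as.integer(round((tt - max(prior)) * sr)) + 1L
        if (slot >= 1 && slot <= length(prof)) prof[slot] else 0L
      }, integer(1))
      keep <- signs != 0L
      trains[[j]] <- spike_train(times[keep], duration,
                                 signs = if (any(keep)) signs[keep])
      policies[j] <- "stored"
    } else {
      trains[[j]] <- spike_train(times, duration)
      policies[j] <- "all_positive"
    }
  }
  raster <- spike_raster(trains, labels = labels, sample_rate = sr)
  decode_spikes(raster, model$thresholds_tg, K, sign_policy = policies,
                reset_times = if (!is.null(events)) events$start)
}
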