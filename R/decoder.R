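#' Fit a spiking neural network decoder
#'
#' Trains the full decoding pipeline on an aligned pair of multichannel
#' signals: input channels are spike-encoded and mapped onto a 3D spiking
#' reservoir initialised with small-world connectivity and evolved once
#' with fire-triggered STDP; the reservoir's spiking response is cut into
#' trials and an evolving population of SPAN neurons is grown per target
#' channel (plus a movement-onset population), each member wired to one
#' anatomical cluster and trained with the spike-domain delta rule to emit
#' the target's encoded spike train; members are then validated on the
#' training trials and weighted into an integrate-and-fire readout.
#'
#' @param inputs a [continuous_signal()] of input (EEG-like) channels.
#' @param targets a [continuous_signal()] of target (muscle-activity or
#'   kinematics-like) channels, same length and sample rate as `inputs`.
#' @param events data.frame with columns `start`, `onset`, `end` (seconds),
#'   one row per training trial.
#' @param montage data.frame `label`, `x`, `y`, `z` giving input channel
#'   positions in template coordinates; defaults to the packaged
#'   10-20-style montage looked up by channel label.
#' @param target_kind named character vector over target labels, entries
#'   `"emg"` (rectified, decoded with all-positive steps) or `"kin"`
#'   (signed, decoded with a per-slot sign profile learned from training
#'   trials). Default: channels that never go negative are `"emg"`.
#' @param control a [snn_control()] parameter object.
#' @param seed integer seed governing all randomness of the fit.
#' @param onset_population also grow a movement-onset population whose
#'   desired train is a single spike at each trial's onset?
#'
#' @return An object of class `snn_decoder`; see [predict.snn_decoder()],
#'   [summary.snn_decoder()], [connectivity_summary()].
#' @export
#' @examples
#' \donttest{
#' ses <- generate_session(synth_config(n_trials = 4, seed = 2))
#' fit <- snn_decoder(ses$inputs, ses$targets, ses$events,
#'                    montage = ses$montage, seed = 2)
#' fit
#' }
snn_decoder <- function(inputs, targets, events, montage = NULL,
                        target_kind = NULL, control = snn_control(),
                        seed = 1, onset_population = TRUE) {
  stopifnot(inherits(inputs, "continuous_signal"),
            inherits(targets, "continuous_signal"))
  if (nrow(inputs$values) != nrow(targets$values) ||
      inputs$sample_rate != targets$sample_rate)
    stop("inputs and targets must share length and sample rate",
         call. = FALSE)
  stopifnot(all(c("start", "end") %in% names(events)))
  if (is.null(events$onset)) events$onset <- events$start
  sr <- inputs$sample_rate
  dt_ms <- 1000 / sr

  if (is.null(montage)) {
    montage <- default_montage(control$template$semi_axes)
    missing <- setdiff(inputs$channel_labels, montage$label)
    if (length(missing))
      stop("no montage position for channel(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    montage <- montage[match(inputs$channel_labels, montage$label), ]
  }

  if (is.null(target_kind)) {
    target_kind <- ifelse(apply(targets$values, 2, min) >= 0, "emg", "kin")
    names(target_kind) <- targets$channel_labels
  }

  # --- codec ---
  thresholds_in <- encoding_thresholds(inputs, control$codec_factor)
  thresholds_tg <- encoding_thresholds(targets, control$codec_factor_targets)
  in_raster <- encode_spikes(inputs, thresholds_in)
  tg_raster <- encode_spikes(targets, thresholds_tg)

  # --- reservoir ---
  tpl <- brain_template(control$template$semi_axes,
                        control$template$resolution,
                        control$template$shell_fraction)
  input_map <- map_inputs(tpl, montage)
  syn <- init_small_world(
    tpl, seed = seed,
    radius_fraction = control$reservoir$radius_fraction,
    p0 = control$reservoir$p0, lambda_d = control$reservoir$lambda_d,
    inhibitory_fraction = control$reservoir$inhibitory_fraction,
    w_scale = control$reservoir$w_scale)
  lif <- list(threshold = control$reservoir$lif_threshold,
              tau_m = control$reservoir$tau_m,
              refractory_ticks = control$reservoir$refractory_ticks,
              w_clip = control$reservoir$w_clip)
  reservoir <- new_reservoir(tpl, syn, input_map, lif)
  run <- run_reservoir(reservoir, in_raster, stdp = control$stdp)
  reservoir <- run$reservoir
  clusters <- extract_clusters(reservoir)

  # --- per-trial data ---
  K <- nrow(inputs$values)
  S_full <- conv_filter_matrix(run$spike_ticks, K, dt_ms,
                               control$span$tau_s)
  trial_idx <- lapply(seq_len(nrow(events)), function(i) {
    k0 <- as.integer(round(events$start[i] * sr)) + 1L
    k1 <- min(as.integer(round(events$end[i] * sr)) + 1L, K)
    c(k0, k1)
  })
  trial_spikes_ms <- lapply(trial_idx, function(ix) {
    lapply(run$spike_ticks, function(tk) {
      tk <- tk[tk >= ix[1] & tk <= ix[2]]
      (tk - ix[1]) * dt_ms
    })
  })

  set.seed(seed + 1L)

  # --- populations ---
  pop_specs <- targets$channel_labels
  if (onset_population && nrow(events) > 0)
    pop_specs <- c(pop_specs, "movement_onset")
  populations <- list()
  for (lb in pop_specs) {
    pop <- new_population(lb, th_n = control$readout$th_n)
    desired_by_trial <- lapply(seq_len(nrow(events)), function(i) {
      if (lb == "movement_onset")
        return((events$onset[i] - events$start[i]) * 1000)
      tt <- tg_raster$trains[[lb]]$times
      tt <- tt[tt >= events$start[i] & tt <= events$end[i]]
      (tt - events$start[i]) * 1000
    })
    for (i in seq_along(trial_spikes_ms)) {
      ix <- trial_idx[[i]]
      grid <- (seq_len(ix[2] - ix[1] + 1L) - 1L) * dt_ms
      pop <- spawn_span_fast(pop, trial_spikes_ms[[i]], desired_by_trial[[i]],
                             clusters, control$span, grid,
                             S_full[ix[1]:ix[2], , drop = FALSE])
    }
    if (length(pop$members)) {
      samples <- lapply(seq_along(trial_spikes_ms), function(i)
        list(spikes = trial_spikes_ms[[i]], desired = desired_by_trial[[i]],
             range = trial_idx[[i]]))
      # absolute desired times (ms) over the whole session, for the
      # session-level graded score (penalises firing outside trials)
      desired_abs <- sort(unlist(lapply(seq_along(samples), function(i)
        desired_by_trial[[i]] + (trial_idx[[i]][1] - 1L) * dt_ms)))
      pop <- validate_population_fast(pop, samples, control$span,
                                      control$readout$kappa, S_full, dt_ms,
                                      desired_abs)
    }
    populations[[lb]] <- pop
  }

  # --- readout normalisation: population current scale on training data.
  # The readout threshold th_n is expressed in units of the typical
  # per-trial peak current (median over training trials), which is robust
  # to single outlier trials.
  member_trains <- member_outputs_full(populations, S_full, dt_ms,
                                       control$span)
  for (lb in names(populations)) {
    cur <- population_current_from(populations[[lb]],
                                   member_trains[[lb]], dt_ms,
                                   control$span$tau_s, K)
    peaks <- vapply(trial_idx, function(ix) max(cur[ix[1]:ix[2]]),
                    numeric(1))
    cmed <- stats::median(peaks)
    populations[[lb]]$current_scale <- if (cmed > 0) cmed else
      max(max(cur), 1)
  }

  # --- per-slot sign profiles for signed (kin) targets ---
  trial_ticks <- as.integer(round((events$end - events$start) * sr)) + 1L
  sign_profiles <- list()
  for (lb in targets$channel_labels) {
    if (target_kind[[lb]] != "kin") next
    L <- max(trial_ticks)
    tally <- numeric(L)
    tr <- tg_raster$trains[[lb]]
    for (i in seq_len(nrow(events))) {
      sel <- tr$times >= events$start[i] & tr$times <= events$end[i]
      slot <- as.integer(round((tr$times[sel] - events$start[i]) * sr)) + 1L
      ok <- slot >= 1 & slot <= L
      tally[slot[ok]] <- tally[slot[ok]] + tr$signs[sel][ok]
    }
    # smooth the tally so contiguous movement phases carry one sign, then
    # ternary: slots with no nearby training spikes carry no decoding step
    tally <- as.numeric(stats::filter(c(0, 0, tally, 0, 0), rep(1 / 5, 5),
                                      sides = 2))[3:(L + 2)]
    sign_profiles[[lb]] <- ifelse(tally < -1e-9, -1L,
                                  ifelse(tally > 1e-9, 1L, 0L))
  }

  structure(list(
    reservoir = reservoir, clusters = clusters, input_map = input_map,
    montage = montage, thresholds_in = thresholds_in,
    thresholds_tg = thresholds_tg, populations = populations,
    target_labels = targets$channel_labels, target_kind = target_kind,
    sign_profiles = sign_profiles, sample_rate = sr,
    control = control, seed = seed,
    n_training_trials = nrow(events), call = match.call()
  ), class = "snn_decoder")
}

# alpha-convolve every neuron's spike train on the session grid via a
# recursive linear filter (columns = neurons); exact for tick-aligned spikes
conv_filter_matrix <- function(spike_ticks, K, dt_ms, tau_s) {
  n <- length(spike_ticks)
  counts <- matrix(0, K, n)
  for (i in seq_len(n)) {
    tk <- spike_ticks[[i]]
    tk <- tk[tk >= 1 & tk <= K]
    if (length(tk)) {
      tab <- tabulate(tk, nbins = K)
      counts[, i] <- tab
    }
  }
  rho <- exp(-dt_ms / tau_s)
  A <- stats::filter(counts, rho, method = "recursive")
  Alag <- rbind(0, A[-K, , drop = FALSE])
  B <- stats::filter(rho * dt_ms * Alag, rho, method = "recursive")
  exp(1) / tau_s * as.matrix(B)
}

# spawn step using a precomputed convolution matrix for the trial
spawn_span_fast <- function(population, trial_spikes, desired, clusters,
                            span_cfg, grid, S_trial) {
  for (m in population$members) {
    if (!isTRUE(m$trained)) next
    cur <- as.numeric(S_trial[, m$afferents, drop = FALSE] %*% m$weights)
    out <- span_fire(cur, span_cfg$th_m, grid)
    if (spikes_match(desired, out, span_cfg$match_tolerance))
      return(population)
  }
  ci <- ((population$next_cluster - 1L) %% length(clusters)) + 1L
  aff <- clusters[[ci]]
  fit <- train_span(trial_spikes[aff], desired, grid, span_cfg,
                    S = S_trial[, aff, drop = FALSE])
  member <- list(weights = fit$weights, afferents = aff,
                 cluster = names(clusters)[ci], trained = fit$trained,
                 accuracy = NA_real_, w_readout = 1, trace = fit$trace)
  population$members <- c(population$members, list(member))
  population$next_cluster <- ci + 1L
  population
}

# validation using precomputed convolutions: per-trial exact-match
# accuracy as in validate_population, but the graded fallback cosine is
# computed over the whole training session so firing outside trials is
# penalised too
validate_population_fast <- function(population, samples, span_cfg, kappa,
                                     S_full, dt_ms, desired_abs) {
  n_mem <- length(population$members)
  K <- nrow(S_full)
  grid_full <- (seq_len(K) - 1L) * dt_ms
  cd_full <- convolve_train(desired_abs, span_cfg$tau_s, grid_full)
  nd_full <- sqrt(sum(cd_full^2))
  acc <- numeric(n_mem)
  sim <- numeric(n_mem)
  for (i in seq_len(n_mem)) {
    m <- population$members[[i]]
    hits <- 0
    for (s in samples) {
      ix <- s$range
      grid <- (seq_len(ix[2] - ix[1] + 1L) - 1L) * dt_ms
      cur <- as.numeric(S_full[ix[1]:ix[2], m$afferents, drop = FALSE] %*%
                          m$weights)
      out <- span_fire(cur, span_cfg$th_m, grid)
      if (spikes_match(s$desired, out, span_cfg$match_tolerance))
        hits <- hits + 1
    }
    acc[i] <- hits / length(samples)
    cur_full <- as.numeric(S_full[, m$afferents, drop = FALSE] %*% m$weights)
    out_full <- span_fire(cur_full, span_cfg$th_m, grid_full)
    co <- convolve_train(out_full, span_cfg$tau_s, grid_full)
    no <- sqrt(sum(co^2))
    sim[i] <- if (nd_full > 0 && no > 0) sum(cd_full * co) / (nd_full * no)
      else as.numeric(nd_full == 0 && no == 0)
  }
  score <- if (n_mem && max(acc) > 0) acc else pmax(sim, 0)
  keep <- score >= kappa * max(score)
  for (i in seq_len(n_mem)) {
    population$members[[i]]$accuracy <- acc[i]
    population$members[[i]]$w_readout <- if (keep[i]) score[i] else 0
  }
  population
}

# member output trains (in ticks -> seconds) over the whole session
member_outputs_full <- function(populations, S_full, dt_ms, span_cfg) {
  grid <- (seq_len(nrow(S_full)) - 1L) * dt_ms
  lapply(populations, function(pop)
    lapply(pop$members, function(m) {
      cur <- as.numeric(S_full[, m$afferents, drop = FALSE] %*% m$weights)
      span_fire(cur, span_cfg$th_m, grid)  # ms times
    }))
}

# population readout current over the session grid from member trains (ms)
population_current_from <- function(pop, trains_ms, dt_ms, tau_s, K) {
  m <- length(pop$members)
  if (!m) return(numeric(K))
  grid <- (seq_len(K) - 1L) * dt_ms
  cur <- numeric(K)
  for (i in seq_len(m)) {
    w <- pop$members[[i]]$w_readout
    if (w != 0) cur <- cur + w * convolve_train(trains_ms[[i]], tau_s, grid)
  }
  cur / m
}

#' @export
print.snn_decoder <- function(x, ...) {
  cat("Spiking neural network decoder\n")
  cat(sprintf("  reservoir: %d neurons, %d synapses, %d input channels\n",
              nrow(x$reservoir$template), sum(x$reservoir$mask),
              length(x$input_map)))
  cat(sprintf("  populations: %s\n",
              paste(sprintf("%s(%d)", names(x$populations),
                            vapply(x$populations, function(p)
                              length(p$members), integer(1))),
                    collapse = ", ")))
  cat(sprintf("  trained on %d trials at %g Hz, seed %d\n",
              x$n_training_trials, x$sample_rate, x$seed))
  invisible(x)
}

#' @export
summary.snn_decoder <- function(object, ...) {
  pops <- lapply(names(object$populations), function(lb) {
    p <- object$populations[[lb]]
    acc <- vapply(p$members, function(m) m$accuracy %||% NA_real_,
                  numeric(1))
    w <- vapply(p$members, function(m) m$w_readout %||% 0, numeric(1))
    data.frame(population = lb, members = length(p$members),
               trained = sum(vapply(p$members, `[[`, logical(1), "trained")),
               audible = sum(w > 0),
               max_accuracy = if (length(acc)) max(acc) else NA_real_,
               mean_accuracy = if (length(acc)) mean(acc) else NA_real_)
  })
  out <- list(table = do.call(rbind, pops),
              n_training_trials = object$n_training_trials,
              seed = object$seed)
  class(out) <- "summary.snn_decoder"
  out
}

#' @export
print.summary.snn_decoder <- function(x, ...) {
  cat(sprintf("snn_decoder fitted on %d trials (seed %d)\n",
              x$n_training_trials, x$seed))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.snn_decoder <- function(object, ...) {
  rows <- lapply(names(object$populations), function(lb) {
    p <- object$populations[[lb]]
    if (!length(p$members)) return(NULL)
    data.frame(population = lb, member = seq_along(p$members),
               cluster = vapply(p$members, `[[`, character(1), "cluster"),
               trained = vapply(p$members, `[[`, logical(1), "trained"),
               accuracy = vapply(p$members, function(m)
                 m$accuracy %||% NA_real_, numeric(1)),
               w_readout = vapply(p$members, function(m)
                 m$w_readout %||% 0, numeric(1)))
  })
  do.call(rbind, rows)
}

#' Plot method: readout population structure
#'
#' Bar chart of member counts per population split into audible and
#' silenced members.
#'
#' @param x an `snn_decoder`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.snn_decoder <- function(x, ...) {
  cf <- coef(x)
  if (is.null(cf)) {
    warning("no members to plot")
    return(invisible(x))
  }
  tab <- table(factor(ifelse(cf$w_readout > 0, "audible", "silenced"),
                      levels = c("audible", "silenced")), cf$population)
  graphics::barplot(tab, legend.text = rownames(tab),
                    ylab = "SPAN members", las = 2, ...)
  invisible(x)
}
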