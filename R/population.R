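#' Evolving SPAN populations
#'
#' A population vector is the group of SPAN neurons responsible for one
#' output event (one target channel, or the movement-onset event). Members
#' are spawned incrementally: when the existing trained members cannot
#' reproduce a trial's desired spike train, a new SPAN is wired to the next
#' anatomical cluster in round-robin order and trained on that trial. After
#' training, members are validated and weighted; an integrate-and-fire
#' readout neuron with binary state summarises the population.
#'
#' @param label event label (e.g. a target channel name).
#' @param th_n readout firing threshold on the normalised population
#'   current.
#' @return `new_population()` returns an empty object of class
#'   `span_population`.
#' @export
new_population <- function(label, th_n = 0.5) {
  stopifnot(th_n > 0)
  structure(list(label = label, members = list(), th_n = th_n,
                 next_cluster = 1L),
            class = "span_population")
}

#' @export
print.span_population <- function(x, ...) {
  acc <- vapply(x$members, function(m) m$accuracy %||% NA_real_, numeric(1))
  cat(sprintf("<span_population> '%s': %d members (%d trained, %d audible)\n",
              x$label, length(x$members),
              sum(vapply(x$members, `[[`, logical(1), "trained")),
              sum(vapply(x$members, function(m) (m$w_readout %||% 0) > 0,
                         logical(1)))))
  if (length(acc) && any(!is.na(acc)))
    cat(sprintf("  accuracy: max %.2f, mean %.2f\n",
                max(acc, na.rm = TRUE), mean(acc, na.rm = TRUE)))
  invisible(x)
}

# compute one member's output spike train (ms) on a trial
# trial_spikes: list of spike-time vectors (ms) per reservoir neuron
member_output <- function(member, trial_spikes, grid, span_cfg) {
  S <- vapply(trial_spikes[member$afferents],
              function(ti) convolve_train(ti, span_cfg$tau_s, grid),
              numeric(length(grid)))
  current <- as.numeric(S %*% member$weights)
  span_fire(current, span_cfg$th_m, grid)
}

#' Spawn-and-train step of incremental learning
#'
#' Presents one trial (afferent reservoir spikes plus the desired output
#' spike train) to a population. If any already-trained member reproduces
#' the desired train within the match tolerance, nothing is spawned.
#' Otherwise a new SPAN is created, wired to all neurons of the next
#' anatomical cluster in round-robin order, trained with [train_span()] on
#' this trial, and appended regardless of convergence.
#'
#' @param population a [new_population()].
#' @param trial_spikes list of per-neuron spike-time vectors (ms, trial
#'   relative) covering the whole reservoir.
#' @param desired numeric vector of desired spike times (ms).
#' @param clusters named list of neuron index vectors from
#'   [extract_clusters()].
#' @param span_cfg SPAN settings (see [snn_control()]`$span`).
#' @param grid trial time grid in ms; defaults to 10 ms ticks over the
#'   trial.
#' @return The updated population.
#' @export
spawn_span <- function(population, trial_spikes, desired, clusters, span_cfg,
                       grid = NULL) {
  stopifnot(inherits(population, "span_population"))
  if (is.null(grid)) {
    horizon <- max(c(unlist(trial_spikes), desired, 0))
    grid <- seq(0, horizon + 4 * span_cfg$tau_s, by = 10)
  }
  for (m in population$members) {
    if (!isTRUE(m$trained)) next
    out <- member_output(m, trial_spikes, grid, span_cfg)
    if (spikes_match(desired, out, span_cfg$match_tolerance))
      return(population)  # already explained; no spawn
  }
  ci <- ((population$next_cluster - 1L) %% length(clusters)) + 1L
  aff <- clusters[[ci]]
  fit <- train_span(trial_spikes[aff], desired, grid, span_cfg)
  member <- list(weights = fit$weights, afferents = aff,
                 cluster = names(clusters)[ci], trained = fit$trained,
                 accuracy = NA_real_, w_readout = 1, trace = fit$trace)
  population$members <- c(population$members, list(member))
  population$next_cluster <- ci + 1L
  population
}

#' Validate and weight the members of a population
#'
#' Scores every member on held-in validation trials: a member's accuracy is
#' the fraction of trials on which its emitted train matches the desired
#' train (equal counts, every spike within the match tolerance). Members
#' with accuracy at least `kappa` times the population's best accuracy keep
#' a readout weight equal to their accuracy; the rest are silenced
#' (retained with weight 0). When no member attains a nonzero match
#' accuracy the population would fall mute, so a graded similarity score
#' takes the place of the accuracy in the weighting (the same `kappa` rule
#' applies): the cosine similarity between the desired and emitted
#' alpha-convolved trains, averaged over validation trials. The score is
#' scale-free (only spike timing matters), 1 for proportional traces and 0
#' for an empty or fully disjoint output; the fallback engages only in the
#' degenerate case.
#'
#' @param population a [new_population()] with members.
#' @param samples list of validation trials, each a list with elements
#'   `spikes` (per-neuron spike times, ms) and `desired` (spike times, ms).
#' @param span_cfg SPAN settings.
#' @param kappa retention factor in `[0, 1]`.
#' @return The population with `accuracy` and `w_readout` set per member.
#' @export
validate_population <- function(population, samples, span_cfg, kappa = 0.8) {
  stopifnot(length(samples) >= 1)
  if (!length(population$members)) return(population)
  horizon <- max(c(unlist(lapply(samples, function(s)
    c(s$desired, 0))), 0))
  grid <- seq(0, horizon + 4 * span_cfg$tau_s, by = 10)
  n_mem <- length(population$members)
  acc <- numeric(n_mem)
  sim <- numeric(n_mem)
  for (i in seq_len(n_mem)) {
    m <- population$members[[i]]
    hits <- 0
    sims <- numeric(0)
    for (s in samples) {
      out <- member_output(m, s$spikes, grid, span_cfg)
      if (spikes_match(s$desired, out, span_cfg$match_tolerance))
        hits <- hits + 1
      cd <- convolve_train(s$desired, span_cfg$tau_s, grid)
      co <- convolve_train(out, span_cfg$tau_s, grid)
      nd <- sqrt(sum(cd^2)); no <- sqrt(sum(co^2))
      sims <- c(sims, if (nd > 0 && no > 0) sum(cd * co) / (nd * no)
                else as.numeric(nd == 0 && no == 0))
    }
    acc[i] <- hits / length(samples)
    sim[i] <- mean(sims)
  }
  score <- if (max(acc) > 0) acc else pmax(sim, 0)
  keep <- score >= kappa * max(score)
  for (i in seq_len(n_mem)) {
    population$members[[i]]$accuracy <- acc[i]
    population$members[[i]]$w_readout <- if (keep[i]) score[i] else 0
  }
  population
}

#' Readout current and binary state of a population
#'
#' The readout neuron receives the average weighted alpha-convolved output
#' of the population members: `I(t) = (1/m) * sum_m w_m * s_m(t)`, and its
#' binary state is 1 wherever the current reaches the readout threshold.
#'
#' @param population a [new_population()] with at least one member.
#' @param member_trains list of member output spike-time vectors (same
#'   order and length as the members), in the grid's time unit.
#' @param tau_s alpha-kernel time constant (same unit as `grid`).
#' @param grid evaluation time grid.
#' @return `readout_current()`: numeric current sequence;
#'   `readout_state()`: integer 0/1 sequence.
#' @export
readout_current <- function(population, member_trains, tau_s, grid) {
  m <- length(population$members)
  if (m == 0) stop("readout current undefined for an empty population",
                   call. = FALSE)
  stopifnot(length(member_trains) == m)
  cur <- numeric(length(grid))
  for (i in seq_len(m)) {
    w <- population$members[[i]]$w_readout %||% 1
    if (w != 0)
      cur <- cur + w * convolve_train(member_trains[[i]], tau_s, grid)
  }
  cur / m
}

#' @param current numeric vector of readout current values.
#' @param th_n readout threshold.
#' @rdname readout_current
#' @export
readout_state <- function(current, th_n) {
  as.integer(current >= th_n)
}

#' Window-wise event label decisions from readout activity
#'
#' Splits the session into windows of `window` seconds and, per window,
#' decides the event label from the binary readout states of all
#' populations: either the label whose mean activation is largest
#' (`"argmax"`, the default) or the label active in the majority of member
#' populations (`"majority"`). Windows with no activity, or with an exact
#' tie between two labels, get the no-event label `"none"`.
#'
#' @param q integer/logical matrix of readout states, one column per
#'   population (columns named by label), one row per tick.
#' @param sample_rate tick rate of `q`, Hz.
#' @param window window length in seconds.
#' @param strategy `"argmax"` or `"majority"`.
#' @return data.frame with `window_start`, `window_end`, `label`.
#' @export
predict_labels <- function(q, sample_rate, window = 0.5,
                           strategy = c("argmax", "majority")) {
  strategy <- match.arg(strategy)
  q <- as.matrix(q)
  n <- nrow(q)
  wlen <- max(1L, as.integer(round(window * sample_rate)))
  starts <- seq(1L, n, by = wlen)
  out <- lapply(starts, function(s) {
    e <- min(s + wlen - 1L, n)
    act <- colMeans(q[s:e, , drop = FALSE])
    lab <- "none"
    if (any(act > 0)) {
      if (strategy == "majority") act <- as.numeric(act > 0.5)
      best <- which(act == max(act))
      if (length(best) == 1 && max(act) > 0) lab <- colnames(q)[best]
    }
    data.frame(window_start = (s - 1) / sample_rate,
               window_end = e / sample_rate, label = lab)
  })
  do.call(rbind, out)
}
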