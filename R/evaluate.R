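#' Lagged normalised cross-correlation between actual and predicted signals
#'
#' Computes the Pearson correlation between the two series at every
#' integer-sample lag in `[-max_lag, +max_lag]` (positive lag: predicted
#' shifted later relative to actual), over the overlapping segment at each
#' lag. Returns the full sequence, the maximum coefficient and its lag,
#' and the coefficient's category.
#'
#' @param actual,predicted numeric vectors of equal length.
#' @param max_lag_ms lag window, milliseconds.
#' @param sample_rate Hz.
#' @return An object of class `xcorr_result`: list with `lags_ms`, `r`
#'   (per-lag coefficients), `r_max`, `lag_at_max_ms`, `category`.
#' @export
#' @examples
#' x <- sin(1:300 / 10)
#' xcorr_lagged(x, c(x[-(1:5)], x[1:5]), max_lag_ms = 100, sample_rate = 100)$lag_at_max_ms
xcorr_lagged <- function(actual, predicted, max_lag_ms = 100,
                        sample_rate = 100) {
  stopifnot(length(actual) == length(predicted))
  L <- as.integer(round(max_lag_ms * sample_rate / 1000))
  n <- length(actual)
  if (n < 2 * L)
    stop("signals shorter than twice the lag window", call. = FALSE)
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0)
    stop("cross-correlation undefined for a constant signal", call. = FALSE)
  lags <- -L:L
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      a <- actual[1:(n - l)]
      b <- predicted[(1 + l):n]
    } else {
      a <- actual[(1 - l):n]
      b <- predicted[1:(n + l)]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  imax <- which.max(r)
  structure(list(lags_ms = lags * 1000 / sample_rate, r = r,
                 r_max = r[imax], lag_at_max_ms = lags[imax] * 1000 / sample_rate,
                 category = categorize_correlation(r[imax])),
            class = "xcorr_result")
}

#' @export
print.xcorr_result <- function(x, ...) {
  cat(sprintf("<xcorr> r_max = %.3f ('%s') at lag %g ms\n",
              x$r_max, x$category, x$lag_at_max_ms))
  invisible(x)
}

#' Bin a correlation coefficient into reporting categories
#'
#' `high`: r >= 0.7; `moderate`: 0.7 > r >= 0.5; `weak`: 0.5 > r >= 0.3;
#' `very_weak` below 0.3.
#'
#' @param r finite correlation coefficient(s).
#' @return Character vector of categories.
#' @export
categorize_correlation <- function(r) {
  stopifnot(all(is.finite(r)))
  ifelse(r >= 0.7, "high",
         ifelse(r >= 0.5, "moderate",
                ifelse(r >= 0.3, "weak", "very_weak")))
}

#' Average alpha-convolved activity of a population raster
#'
#' Convolves each member spike train with the alpha kernel and averages,
#' giving the continuous population trace that is compared against the
#' smoothed target signal.
#'
#' @param trains list of spike-time vectors (one per member), in the grid's
#'   time unit.
#' @param tau_s alpha-kernel time constant.
#' @param grid evaluation time grid.
#' @param weights optional per-member weights (e.g. readout weights);
#'   default equal.
#' @return Numeric vector over the grid (zero for an empty raster).
#' @export
smooth_population_activity <- function(trains, tau_s, grid, weights = NULL) {
  if (!length(trains)) return(numeric(length(grid)))
  if (is.null(weights)) weights <- rep(1, length(trains))
  stopifnot(length(weights) == length(trains))
  acc <- numeric(length(grid))
  for (i in seq_along(trains))
    if (weights[i] != 0)
      acc <- acc + weights[i] * convolve_train(trains[[i]], tau_s, grid)
  acc / length(trains)
}

#' Moving-average smoothing of a signal
#'
#' Centred moving average used to smooth rectified targets before
#' correlation.
#'
#' @param x numeric vector.
#' @param window_ms window length in ms.
#' @param sample_rate Hz.
#' @return Smoothed numeric vector (edges padded by repetition).
#' @export
smooth_signal <- function(x, window_ms = 50, sample_rate = 100) {
  w <- max(1L, as.integer(round(window_ms * sample_rate / 1000)))
  if (w == 1L) return(x)
  pad <- c(rep(x[1], w), x, rep(x[length(x)], w))
  sm <- stats::filter(pad, rep(1 / w, w), sides = 2)
  as.numeric(sm[(w + 1):(w + length(x))])
}

#' Score a prediction against the actual targets
#'
#' Per target channel, computes the max-lag cross-correlation between the
#' actual signal and the decoder's predicted trace. Rectified
#' (muscle-activity-like) targets are scored against the weighted
#' population activity of the corresponding SPAN population (alpha
#' convolution of member output trains), mirroring how population activity
#' is compared to smoothed rectified muscle signals; kinematics-like
#' targets are scored against the decoded continuous trajectory. Both
#' sides are moving-average smoothed first.
#'
#' @param model a fitted [snn_decoder()].
#' @param prediction the [predict.snn_decoder()] result on the test input.
#' @param actual a [continuous_signal()] of the actual target channels for
#'   the same window.
#' @return data.frame with one row per target: `target`, `kind`, `r_max`,
#'   `lag_at_max_ms`, `category`.
#' @export
evaluate_decoding <- function(model, prediction, actual) {
  sr <- model$sample_rate
  ctrl <- model$control$evaluation
  K <- prediction$n_ticks
  grid_ms <- (seq_len(K) - 1) * 1000 / sr
  rows <- lapply(model$target_labels, function(lb) {
    kind <- model$target_kind[[lb]]
    act <- smooth_signal(actual$values[, lb], ctrl$smooth_ms, sr)
    pred <- if (kind == "emg") {
      pop <- model$populations[[lb]]
      wts <- vapply(pop$members, function(m) m$w_readout %||% 1, numeric(1))
      pa <- smooth_population_activity(
        lapply(prediction$member_spikes[[lb]], function(tt) tt * 1000),
        ctrl$tau_s_pop %||% model$control$span$tau_s, grid_ms,
        weights = wts)
      smooth_signal(pa, ctrl$smooth_ms, sr)
    } else {
      smooth_signal(prediction$decoded$values[, lb], ctrl$smooth_ms, sr)
    }
    res <- tryCatch(
      xcorr_lagged(act, pred, ctrl$max_lag_ms, sr),
      error = function(e) list(r_max = NA_real_, lag_at_max_ms = NA_real_,
                               category = NA_character_))
    data.frame(target = lb, kind = kind, r_max = res$r_max,
               lag_at_max_ms = res$lag_at_max_ms, category = res$category)
  })
  do.call(rbind, rows)
}

#' Pseudo-online latency summary
#'
#' Summarises per-tick wall-clock prediction times and flags real-time
#' feasibility (median latency below the inter-sample interval). The flag
#' is hardware-dependent and reported for information only.
#'
#' @param latency numeric vector of per-tick seconds (from a streaming
#'   [predict.snn_decoder()] run).
#' @param sample_rate Hz.
#' @return List with `mean_ms`, `median_ms`, `max_ms`, `tick_ms`,
#'   `real_time` (logical).
#' @export
latency_report <- function(latency, sample_rate) {
  if (!length(latency)) stop("empty latency log", call. = FALSE)
  tick_ms <- 1000 / sample_rate
  med <- stats::median(latency) * 1000
  list(mean_ms = mean(latency) * 1000, median_ms = med,
       max_ms = max(latency) * 1000, tick_ms = tick_ms,
       real_time = med < tick_ms)
}

#' Decode a synthetic session end to end
#'
#' Convenience harness: fits a decoder on the first `train_trials` of a
#' session, predicts the remaining test window, and scores each target.
#' Also used by [learning_curve()].
#'
#' @param session a [generate_session()] result.
#' @param train_trials number of training trials (from the start).
#' @param test_trials trial indices of the test window; default everything
#'   after the training trials.
#' @param control a [snn_control()].
#' @param seed fit seed.
#' @param mode prediction mode.
#' @return List with `model`, `prediction`, `scores` (from
#'   [evaluate_decoding()]), `test_session`.
#' @export
decode_session <- function(session, train_trials = 20, test_trials = NULL,
                           control = snn_control(), seed = 1,
                           mode = "batch") {
  n_tr <- nrow(session$events)
  stopifnot(train_trials >= 1, train_trials < n_tr)
  if (is.null(test_trials)) test_trials <- (train_trials + 1):n_tr
  train <- session_window(session, 1, train_trials)
  test <- session_window(session, min(test_trials), max(test_trials))
  model <- snn_decoder(train$inputs, train$targets, train$events,
                       montage = session$montage,
                       target_kind = session$target_kind,
                       control = control, seed = seed)
  prediction <- predict(model, test$inputs, events = test$events, mode = mode)
  scores <- evaluate_decoding(model, prediction, test$targets)
  list(model = model, prediction = prediction, scores = scores,
       test_session = test)
}

#' Decoding performance as a function of training set size
#'
#' Fits the decoder at increasing numbers of training trials and scores
#' each fit on one fixed held-out test window (the trials after the
#' largest training size), per seed.
#'
#' @param session a [generate_session()] result.
#' @param trial_counts integer vector of training sizes.
#' @param seeds integer vector of fit seeds.
#' @param control a [snn_control()].
#' @return Tidy data.frame: `seed`, `train_trials`, `target`, `kind`,
#'   `r_max`.
#' @export
learning_curve <- function(session, trial_counts = c(3, 15),
                           seeds = 1:5, control = snn_control()) {
  n_tr <- nrow(session$events)
  kmax <- max(trial_counts)
  if (kmax >= n_tr)
    stop("not enough trials for the requested training sizes", call. = FALSE)
  test_trials <- (kmax + 1):n_tr
  rows <- list()
  for (s in seeds) for (k in trial_counts) {
    res <- decode_session(session, train_trials = k,
                          test_trials = test_trials,
                          control = control, seed = s)
    sc <- res$scores
    rows[[length(rows) + 1L]] <-
      data.frame(seed = s, train_trials = k, target = sc$target,
                 kind = sc$kind, r_max = sc$r_max)
  }
  do.call(rbind, rows)
}

#' Summarise model connectivity by brain region
#'
#' Tallies, per SPAN population and template region, how many members are
#' wired to that region's cluster and their summed absolute readout
#' weight. The per-population counts sum to the population's member count.
#'
#' @param model a fitted [snn_decoder()].
#' @param include_silenced also count members with zero readout weight?
#' @return data.frame `population`, `region`, `members`, `weight_sum`.
#' @export
connectivity_summary <- function(model, include_silenced = TRUE) {
  rows <- list()
  for (lb in names(model$populations)) {
    p <- model$populations[[lb]]
    for (m in p$members) {
      w <- m$w_readout %||% 0
      if (!include_silenced && w == 0) next
      key <- paste(lb, m$cluster)
      if (is.null(rows[[key]]))
        rows[[key]] <- data.frame(population = lb, region = m$cluster,
                                  members = 0L, weight_sum = 0)
      rows[[key]]$members <- rows[[key]]$members + 1L
      rows[[key]]$weight_sum <- rows[[key]]$weight_sum + abs(w)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
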