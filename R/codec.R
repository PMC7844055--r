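#' Threshold-based spike encoding and decoding
#'
#' The codec turns a continuous channel into a spike train by thresholding
#' successive differences, and reconstructs a continuous trace from a signed
#' spike train by stepping the signal up or down by the channel threshold at
#' every spike.
#'
#' For a channel `x` sampled at `sample_rate`, the per-channel threshold is
#' computed from the absolute successive differences `d[t] = |x[t] - x[t-1]|`
#' as `th = mean(d) + c * sd(d)`, where `c` is the encoding factor and `sd`
#' is the population (divide-by-count) standard deviation, so thresholds are
#' reproducible across implementations. A spike is emitted at sample `t`
#' (0-based, first possible spike at sample 1, timestamped `t / sample_rate`
#' seconds) whenever `|x[t] - x[t-1]| >= th`, with the polarity of the
#' difference recorded as the spike sign. A channel whose differences are all
#' zero gets `th = 0` and emits no spikes: a channel with no variability
#' carries no events.
#'
#' @param x numeric vector, one channel of amplitudes (length >= 2, finite).
#' @param c encoding factor (real); larger values raise the threshold and
#'   thin the spike train.
#'
#' @return `compute_threshold()` returns a list with fields `th`, `c`,
#'   `mean`, `std` and `initial` (the first sample, retained so decoding can
#'   anchor the reconstruction).
#' @export
#' @examples
#' compute_threshold(c(0, 2, 3, 7), c = 0)  # th = mean(c(2, 1, 4)) = 7/3
compute_threshold <- function(x, c = 0.5) {
  if (length(x) < 2)
    stop("need at least 2 samples to form differences", call. = FALSE)
  if (!all(is.finite(x)))
    stop("non-finite samples in channel", call. = FALSE)
  d <- abs(diff(x))
  mu <- mean(d)
  sigma <- sqrt(mean((d - mu)^2))  # population sd
  th <- mu + c * sigma
  if (th < 0) th <- 0
  list(th = th, c = c, mean = mu, std = sigma, initial = x[1])
}

#' Per-channel encoding thresholds for a multichannel signal
#'
#' @param signal a [continuous_signal()].
#' @param c encoding factor, recycled across channels or one value per
#'   channel.
#' @return An object of class `encoding_thresholds`: a named list of
#'   [compute_threshold()] entries, one per channel, plus the sample rate.
#' @export
encoding_thresholds <- function(signal, c = 0.5) {
  stopifnot(inherits(signal, "continuous_signal"))
  p <- ncol(signal$values)
  c <- rep_len(c, p)
  entries <- lapply(seq_len(p), function(j)
    compute_threshold(signal$values[, j], c[j]))
  names(entries) <- signal$channel_labels
  structure(list(channels = entries, sample_rate = signal$sample_rate),
            class = "encoding_thresholds")
}

#' @export
print.encoding_thresholds <- function(x, ...) {
  th <- vapply(x$channels, `[[`, numeric(1), "th")
  cat(sprintf("<encoding_thresholds> %d channels, th in [%.4g, %.4g]\n",
              length(th), min(th), max(th)))
  invisible(x)
}

#' Encode a multichannel signal into a signed spike raster
#'
#' @param signal a [continuous_signal()].
#' @param thresholds an [encoding_thresholds()] object covering every channel
#'   of `signal`.
#' @return A signed [spike_raster()]; take [unsigned_spikes()] of it for SPAN
#'   training.
#' @export
#' @examples
#' sig <- continuous_signal(cbind(a = c(0, 2, 3, 7)), sample_rate = 1)
#' th <- encoding_thresholds(sig, c = 0)
#' encode_spikes(sig, th)$trains$a$times  # one spike at t = 3
encode_spikes <- function(signal, thresholds) {
  stopifnot(inherits(signal, "continuous_signal"),
            inherits(thresholds, "encoding_thresholds"))
  if (!all(signal$channel_labels %in% names(thresholds$channels)))
    stop("thresholds missing for some channels", call. = FALSE)
  n <- nrow(signal$values)
  sr <- signal$sample_rate
  duration <- (n - 1) / sr
  trains <- lapply(signal$channel_labels, function(lb) {
    th <- thresholds$channels[[lb]]$th
    dx <- diff(signal$values[, lb])
    if (th <= 0) return(spike_train(numeric(0), duration))
    hit <- which(abs(dx) >= th)
    spike_train(hit / sr, duration,
                signs = if (length(hit)) ifelse(dx[hit] >= 0, 1L, -1L))
  })
  spike_raster(trains, labels = signal$channel_labels, sample_rate = sr)
}

#' Decode a spike raster back into continuous signals
#'
#' Reconstructs each channel as a staircase anchored at the stored initial
#' value: at every spike the trace steps by `sign * th`, otherwise it holds.
#' Unsigned rasters (e.g. SPAN predictions for rectified, non-negative
#' targets) must opt into the all-positive fallback, where every spike steps
#' the trace up by `th`.
#'
#' Optionally the reconstruction is re-anchored to the initial value at given
#' trial-start times, mirroring per-trial decoding where each trial starts
#' from the signal's rest state.
#'
#' @param raster a [spike_raster()] whose labels all have threshold entries.
#' @param thresholds an [encoding_thresholds()] object.
#' @param n_samples number of output samples per channel.
#' @param sign_policy `"stored"` (use the raster's signs; error if absent) or
#'   `"all_positive"`; recycled per channel.
#' @param reset_times optional numeric vector of times (seconds) at which each
#'   channel is reset to its initial value.
#' @return A [continuous_signal()].
#' @export
decode_spikes <- function(raster, thresholds, n_samples,
                          sign_policy = "stored", reset_times = NULL) {
  stopifnot(inherits(raster, "spike_raster"),
            inherits(thresholds, "encoding_thresholds"))
  sr <- raster$sample_rate %||% thresholds$sample_rate
  if (is.null(sr)) stop("raster carries no sample rate", call. = FALSE)
  sign_policy <- rep_len(sign_policy, length(raster$labels))
  reset_idx <- if (length(reset_times)) round(reset_times * sr) + 1L
  vals <- vapply(seq_along(raster$labels), function(i) {
    lb <- raster$labels[i]
    entry <- thresholds$channels[[lb]]
    if (is.null(entry)) stop("no thresholds for channel ", lb, call. = FALSE)
    tr <- raster$trains[[i]]
    if (is.null(tr$signs) && tr$n > 0 && sign_policy[i] != "all_positive")
      stop("unsigned raster: choose sign_policy = \"all_positive\" explicitly",
           call. = FALSE)
    sgn <- if (sign_policy[i] == "all_positive") rep(1, tr$n) else tr$signs
    steps <- numeric(n_samples)
    idx <- round(tr$times * sr) + 1L
    keep <- idx >= 1 & idx <= n_samples
    if (any(keep))
      steps[idx[keep]] <- steps[idx[keep]] + sgn[keep] * entry$th
    x <- entry$initial + cumsum(steps)
    if (!is.null(reset_idx)) {
      for (r in reset_idx[reset_idx >= 1 & reset_idx <= n_samples]) {
        # re-anchor: shift the tail so the trace restarts at the initial value
        x[r:n_samples] <- x[r:n_samples] - x[r] + entry$initial
      }
    }
    x
  }, numeric(n_samples))
  colnames(vals) <- raster$labels
  continuous_signal(vals, sample_rate = sr, channel_labels = raster$labels)
}

#' Write / read encoding thresholds as JSON
#'
#' Document shape: `{channel: {th, c, mean, std, initial}, ...}` plus a
#' `.sample_rate` entry.
#'
#' @param thresholds an [encoding_thresholds()] object.
#' @param path file path.
#' @return `read_thresholds_json()` returns an [encoding_thresholds()].
#' @export
write_thresholds_json <- function(thresholds, path) {
  doc <- thresholds$channels
  doc[[".sample_rate"]] <- thresholds$sample_rate
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sr <- doc[[".sample_rate"]]
  doc[[".sample_rate"]] <- NULL
  structure(list(channels = doc, sample_rate = sr),
            class = "encoding_thresholds")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
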