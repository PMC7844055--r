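#' Spike trains and spike rasters
#'
#' A `spike_train` is a strictly increasing vector of spike times in seconds,
#' optionally carrying a per-spike polarity in \{+1, -1\}. A `spike_raster`
#' is an ordered collection of trains sharing one duration (and, when it
#' originates from sampled data, one sample rate). Unsigned trains are what
#' the SPAN layer consumes; signs are retained internally for decoding.
#'
#' @param times numeric vector of spike times (seconds), strictly increasing,
#'   within `[0, duration]`.
#' @param duration duration of the observation window in seconds.
#' @param signs optional integer vector of per-spike polarities (+1 / -1).
#'
#' @return `spike_train()` returns an object of class `spike_train` with
#'   fields `times`, `signs`, `duration` and spike count `n`.
#' @export
#' @examples
#' spike_train(c(0.1, 0.25), duration = 1, signs = c(1L, -1L))
spike_train <- function(times, duration, signs = NULL) {
  times <- as.numeric(times)
  if (length(times) && (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE)))
    stop("spike times must be finite and strictly increasing", call. = FALSE)
  if (length(times) && (times[1] < 0 || times[length(times)] > duration))
    stop("spike times must lie within [0, duration]", call. = FALSE)
  if (!is.null(signs)) {
    signs <- as.integer(signs)
    if (length(signs) != length(times) || !all(signs %in% c(-1L, 1L)))
      stop("'signs' must be +1/-1, one per spike", call. = FALSE)
  }
  structure(list(times = times, signs = signs, duration = duration,
                 n = length(times)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.3f s%s\n", x$n, x$duration,
              if (is.null(x$signs)) " (unsigned)" else " (signed)"))
  invisible(x)
}

#' @param trains list of [spike_train()] objects, one per channel.
#' @param labels character vector of channel labels.
#' @param sample_rate optional sample rate (Hz) of the grid the spikes are
#'   aligned to.
#' @rdname spike_train
#' @export
spike_raster <- function(trains, labels = names(trains), sample_rate = NULL) {
  if (!length(trains)) stop("empty raster", call. = FALSE)
  if (is.null(labels)) labels <- paste0("unit", seq_along(trains))
  stopifnot(length(labels) == length(trains))
  durs <- vapply(trains, function(tr) tr$duration, numeric(1))
  if (length(unique(durs)) != 1)
    stop("all trains in a raster must share one duration", call. = FALSE)
  names(trains) <- labels
  structure(list(trains = trains, labels = labels, duration = durs[1],
                 sample_rate = sample_rate),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  n <- vapply(x$trains, function(tr) tr$n, integer(1))
  cat(sprintf("<spike_raster> %d channels, %.3f s, %d spikes total\n",
              length(x$trains), x$duration, sum(n)))
  invisible(x)
}

#' Drop spike polarities
#'
#' Returns the unsigned view of a train or raster: identical spike times,
#' no polarity. This is the representation the SPAN output layer is trained
#' on, since it cannot mix positive and negative spikes.
#'
#' @param x a `spike_train` or `spike_raster`.
#' @return Object of the same class without signs.
#' @export
unsigned_spikes <- function(x) {
  if (inherits(x, "spike_train"))
    return(spike_train(x$times, x$duration))
  if (inherits(x, "spike_raster")) {
    tr <- lapply(x$trains, function(t) spike_train(t$times, t$duration))
    return(spike_raster(tr, labels = x$labels, sample_rate = x$sample_rate))
  }
  stop("not a spike_train or spike_raster", call. = FALSE)
}

#' Read / write spike rasters as two-column CSV
#'
#' Columns `channel`, `time` (seconds) and, for signed rasters, `sign`.
#' Channels with no spikes are preserved through the `channels` attribute
#' written as a commented header line.
#'
#' @param raster a [spike_raster()].
#' @param path file path.
#' @return `read_raster_csv()` returns a [spike_raster()].
#' @export
write_raster_csv <- function(raster, path) {
  rows <- lapply(seq_along(raster$trains), function(i) {
    tr <- raster$trains[[i]]
    if (!tr$n) return(NULL)
    data.frame(channel = raster$labels[i], time = tr$times,
               sign = if (is.null(tr$signs)) NA_integer_ else tr$signs)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(channel = character(), time = numeric(),
                     sign = integer())
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# channels=%s duration=%.10g sample_rate=%.10g",
                     paste(raster$labels, collapse = ";"), raster$duration,
                     if (is.null(raster$sample_rate)) NA else raster$sample_rate),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "# channels=(.*) duration=([0-9.eE+-]+) sample_rate=([0-9.eE+-]+|NA)", hdr))[[1]]
  if (length(m) != 4) stop("malformed raster header", call. = FALSE)
  labels <- strsplit(m[2], ";", fixed = TRUE)[[1]]
  duration <- as.numeric(m[3])
  sr <- suppressWarnings(as.numeric(m[4]))
  df <- utils::read.csv(path, comment.char = "#")
  signed <- nrow(df) > 0 && !all(is.na(df$sign))
  trains <- lapply(labels, function(lb) {
    sub <- df[df$channel == lb, , drop = FALSE]
    sub <- sub[order(sub$time), , drop = FALSE]
    spike_train(sub$time, duration,
                signs = if (signed && nrow(sub)) sub$sign else NULL)
  })
  spike_raster(trains, labels = labels,
               sample_rate = if (is.na(sr)) NULL else sr)
}
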