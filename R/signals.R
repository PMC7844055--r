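#' Uniformly sampled multichannel continuous signal
#'
#' The basic substrate of the pipeline: a numeric matrix of amplitudes with
#' one column per channel and one row per sample, plus a sample rate and a
#' time origin. Row `i` is the sample at time `t0 + (i - 1) / sample_rate`
#' seconds.
#'
#' @param values numeric matrix (samples x channels) or a data.frame of
#'   numeric columns. At least two rows.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param channel_labels character vector of channel names; defaults to the
#'   column names of `values`.
#' @param t0 time of the first sample in seconds.
#'
#' @return An object of class `continuous_signal`.
#' @export
#' @examples
#' sig <- continuous_signal(cbind(ch1 = sin(1:100 / 5)), sample_rate = 100)
#' sig
continuous_signal <- function(values, sample_rate, channel_labels = NULL,
                              t0 = 0) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 2)
    stop("a continuous signal needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values)))
    stop("non-finite sample values", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("'sample_rate' must be a single positive number", call. = FALSE)
  if (is.null(channel_labels)) channel_labels <- colnames(values)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(ncol(values)))
  if (length(channel_labels) != ncol(values))
    stop("one label per channel required", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("duplicated channel labels", call. = FALSE)
  colnames(values) <- channel_labels
  structure(
    list(values = values, sample_rate = sample_rate,
         channel_labels = channel_labels, t0 = t0),
    class = "continuous_signal"
  )
}

#' @export
print.continuous_signal <- function(x, ...) {
  cat(sprintf("<continuous_signal> %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$values), ncol(x$values), x$sample_rate,
              nrow(x$values) / x$sample_rate))
  cat("channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' Sample times of a continuous signal
#'
#' @param signal a [continuous_signal()].
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(signal) {
  signal$t0 + (seq_len(nrow(signal$values)) - 1) / signal$sample_rate
}

#' Read / write multichannel signals as delimited text
#'
#' The canonical interchange format: one header row of channel labels, first
#' column `time` in seconds, then one numeric column per channel. The sample
#' rate is recovered from the median time step.
#'
#' @param path file path.
#' @return `read_signal_csv()` returns a [continuous_signal()];
#'   `write_signal_csv()` returns `path` invisibly.
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("signal CSV needs a time column plus >= 1 channel",
                         call. = FALSE)
  tm <- df[[1]]
  dt <- stats::median(diff(tm))
  if (!is.finite(dt) || dt <= 0) stop("non-increasing time column",
                                      call. = FALSE)
  continuous_signal(as.matrix(df[-1]), sample_rate = 1 / dt,
                    channel_labels = names(df)[-1], t0 = tm[1])
}

#' @rdname read_signal_csv
#' @param signal a [continuous_signal()] to write.
#' @export
write_signal_csv <- function(signal, path) {
  df <- data.frame(time = signal_times(signal), check.names = FALSE)
  df <- cbind(df, as.data.frame(signal$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
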