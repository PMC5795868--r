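#' Windowed RMS feature series
#'
#' Per-window, per-channel RMS amplitudes with the windowing metadata needed
#' to interpret them.  Constructed by [sliding_rms()] or [rms_streamer()].
#'
#' @param values `n_windows x n_channels` matrix of RMS amplitudes (uV).
#' @param window_ms,step_ms Window length and step in milliseconds.
#' @param times Window end times in seconds (strictly increasing, spaced by
#'   `step_ms`).
#' @param channels Channel labels.
#' @param labels Optional per-window motion labels (factor).
#' @return An object of class `semg_features`.
#' @export
semg_features <- function(values, window_ms, step_ms, times, channels,
                          labels = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("RMS values must be >= 0")
  if (length(times) != nrow(values))
    stop("times length does not match number of windows")
  if (length(channels) != ncol(values))
    stop("channels length does not match number of columns")
  colnames(values) <- channels
  structure(list(values = values, window_ms = window_ms, step_ms = step_ms,
                 times = times, channels = channels, labels = labels),
            class = "semg_features")
}

#' @export
print.semg_features <- function(x, ...) {
  cat(sprintf(
    "semg_features: %d windows x %d channels (window %g ms, step %g ms)\n",
    nrow(x$values), ncol(x$values), x$window_ms, x$step_ms))
  if (!is.null(x$labels))
    cat("  labels:", paste(levels(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.semg_features <- function(x) dim(x$values)

# window/step in whole samples; errors report the fractional remainder
window_samples <- function(ms, fs, what) {
  w <- ms * fs / 1000
  if (abs(w - round(w)) > 1e-9)
    stop(what, " of ", ms, " ms is not a whole number of samples at ",
         fs, " Hz (", w, " samples, remainder ", w - floor(w), ")")
  as.integer(round(w))
}

# modal label per window; ties broken toward the earliest factor level
window_labels <- function(labels, starts, W) {
  if (is.null(labels)) return(NULL)
  lv <- levels(labels)
  code <- as.integer(labels)
  out <- vapply(starts, function(s)
    which.max(tabulate(code[s:(s + W - 1L)], nbins = length(lv))),
    integer(1))
  factor(lv[out], levels = lv)
}

#' Sliding-window RMS features
#'
#' Splits each channel into windows of `window_ms` advancing by `step_ms`
#' (both must be whole sample counts at the record's sampling rate) and
#' computes the RMS amplitude of every window.  Windows are anchored at the
#' start of the record; a ragged final partial window is discarded, so the
#' number of windows is `floor((n - W) / S) + 1`.  When the record carries
#' per-sample motion labels each window is labeled with its modal sample
#' label (ties toward the earlier class).
#'
#' @param record A [semg_record] at least one window long.
#' @param window_ms Window length in ms (default 200).
#' @param step_ms Step between window starts in ms (default 5).
#' @return A [semg_features] object.
#' @export
sliding_rms <- function(record, window_ms = 200, step_ms = 5) {
  fs <- record$fs
  W <- window_samples(window_ms, fs, "window_ms")
  S <- window_samples(step_ms, fs, "step_ms")
  x <- record$samples
  n <- nrow(x)
  if (n < W)
    stop("record has ", n, " samples, shorter than one window (", W, ")")
  nw <- (n - W) %/% S + 1L
  starts <- 1L + (seq_len(nw) - 1L) * S
  # prefix sums of squares give every window RMS in O(n) per channel
  cs <- apply(x^2, 2, function(col) cumsum(c(0, col)))
  vals <- sqrt((cs[starts + W, , drop = FALSE] -
                  cs[starts, , drop = FALSE]) / W)
  times <- record$start_time + (starts + W - 2L) / fs
  semg_features(vals, window_ms, step_ms, times, record$channels,
                labels = window_labels(record$labels, starts, W))
}

#' Streaming RMS feature extractor
#'
#' Incremental counterpart of [sliding_rms()]: samples are fed in chunks and
#' each window's RMS is emitted as soon as its last sample has arrived.  The
#' finalized series matches the batch result to better than 1e-9 relative.
#'
#' @param fs Sampling rate (Hz) of the incoming stream.
#' @param n_channels Number of channels.
#' @param window_ms,step_ms As in [sliding_rms()].
#' @param channels Optional channel labels.
#' @return A list with functions `feed(samples)` (rows of new samples; returns
#'   the windows completed by this chunk, invisibly) and `finalize()`
#'   (returns the accumulated [semg_features]; zero windows is not an error).
#' @export
rms_streamer <- function(fs, n_channels, window_ms = 200, step_ms = 5,
                         channels = sprintf("ch%02d", seq_len(n_channels))) {
  W <- window_samples(window_ms, fs, "window_ms")
  S <- window_samples(step_ms, fs, "step_ms")
  buf <- matrix(numeric(0), 0L, n_channels)
  consumed <- 0L   # samples dropped from the front of the buffer
  pending <- 0L    # samples still to discard (only when step > window)
  vals <- list()
  ends <- integer(0)

  feed <- function(samples) {
    if (is.vector(samples)) samples <- matrix(samples, ncol = n_channels)
    if (ncol(samples) != n_channels) stop("chunk has wrong channel count")
    if (pending > 0L) {
      k <- min(pending, nrow(samples))
      samples <- samples[-seq_len(k), , drop = FALSE]
      consumed <<- consumed + k
      pending <<- pending - k
    }
    buf <<- rbind(buf, samples)
    new <- list()
    repeat {
      done <- length(ends)
      start_abs <- done * S + 1L           # absolute start of next window
      start_rel <- start_abs - consumed
      if (start_rel + W - 1L > nrow(buf)) break
      win <- buf[start_rel:(start_rel + W - 1L), , drop = FALSE]
      r <- sqrt(colMeans(win^2))
      vals[[done + 1L]] <<- r
      ends <<- c(ends, start_abs + W - 1L)
      new[[length(new) + 1L]] <- r
      drop <- start_abs + S - 1L - consumed  # keep samples from next start on
      if (drop > 0) {
        k <- min(drop, nrow(buf))
        buf <<- buf[-seq_len(k), , drop = FALSE]
        consumed <<- consumed + k
        pending <<- drop - k
      }
    }
    invisible(new)
  }

  finalize <- function() {
    m <- if (length(vals)) do.call(rbind, vals)
    else matrix(numeric(0), 0L, n_channels)
    semg_features(m, window_ms, step_ms, (ends - 1L) / fs, channels)
  }

  list(feed = feed, finalize = finalize)
}

#' Moving-average smoothing of a feature series
#'
#' Centered moving average per channel with shrunken (partial) windows at the
#' edges, so the output length equals the input length.
#'
#' @param features A [semg_features].
#' @param span_windows Odd span in windows (default 41, about 205 ms at the
#'   default 5 ms step).
#' @return A smoothed [semg_features].
#' @export
moving_average <- function(features, span_windows = 41) {
  if (span_windows < 1) stop("span_windows must be >= 1")
  if (span_windows %% 2 == 0) stop("span_windows must be odd")
  n <- nrow(features$values)
  if (span_windows > n)
    stop("span_windows (", span_windows, ") exceeds series length (", n, ")")
  h <- (span_windows - 1L) / 2
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sm <- apply(features$values, 2, function(col) {
    cs <- cumsum(c(0, col))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  semg_features(matrix(sm, n), features$window_ms, features$step_ms,
                features$times, features$channels, features$labels)
}

#' Total muscle activation per window
#'
#' Sum of the RMS amplitudes across all channels for each window — a gross
#' activity envelope useful for onset displays.
#'
#' @param features A [semg_features].
#' @return Numeric vector of length `n_windows`.
#' @export
total_activation <- function(features) {
  rowSums(features$values)
}
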