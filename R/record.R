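#' Multichannel sEMG recording
#'
#' Container for a multichannel surface-EMG time series.  Samples are stored
#' as an `n_samples x n_channels` numeric matrix in microvolts, together with
#' the sampling rate, channel labels and (optionally) a per-sample motion
#' label.
#'
#' @param samples Numeric matrix, `n_samples x n_channels`, in microvolts.
#'   A plain vector is treated as a single channel.
#' @param fs Sampling rate in Hz (scalar, > 0).
#' @param channels Character vector of channel labels; defaults to the
#'   matrix column names or `"ch01"`, `"ch02"`, ...
#' @param labels Optional per-sample motion labels (character or factor,
#'   length `n_samples`).
#' @param start_time Time of the first sample in seconds (default 0).
#'
#' @return An object of class `semg_record` with fields `samples`, `fs`,
#'   `channels`, `labels` and `start_time`.
#' @export
semg_record <- function(samples, fs, channels = NULL, labels = NULL,
                        start_time = 0) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!all(is.finite(samples)))
    stop("samples must be finite; found ", sum(!is.finite(samples)),
         " non-finite value(s)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  n <- nrow(samples)
  nc <- ncol(samples)
  if (is.null(channels)) {
    channels <- colnames(samples)
    if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(nc))
  }
  if (length(channels) != nc)
    stop("length(channels) [", length(channels),
         "] does not match number of columns [", nc, "]")
  if (!is.null(labels)) {
    if (length(labels) != n)
      stop("labels length [", length(labels),
           "] does not match n_samples [", n, "]")
    if (!is.factor(labels)) labels <- factor(labels, levels = unique(labels))
  }
  colnames(samples) <- channels
  structure(
    list(samples = samples, fs = fs, channels = channels,
         labels = labels, start_time = start_time),
    class = "semg_record")
}

#' @export
print.semg_record <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("semg_record: %d channels, %d samples @ %g Hz (%.3f s)\n",
              ncol(x$samples), n, x$fs, n / x$fs))
  cat("  channels:", paste(utils::head(x$channels, 8), collapse = ", "),
      if (length(x$channels) > 8) "...", "\n")
  if (!is.null(x$labels))
    cat("  labels:", paste(levels(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.semg_record <- function(x) dim(x$samples)

#' Sample times of a recording
#'
#' @param record A [semg_record].
#' @return Numeric vector of sample times in seconds.
#' @export
sample_times <- function(record) {
  record$start_time + (seq_len(nrow(record$samples)) - 1L) / record$fs
}

#' Electrode grid layout
#'
#' Maps channel labels to (row, col) cells of the electrode grid.  Every
#' channel occupies exactly one cell and no two channels share a cell; cells
#' without a channel remain unoccupied.
#'
#' @param rows,cols Grid dimensions (positive integers).
#' @param placements A data frame with columns `channel`, `row`, `col`.
#' @param ied_mm Optional inter-electrode distance in millimetres (metadata).
#'
#' @return An object of class `electrode_layout`.
#' @export
electrode_layout <- function(rows, cols, placements, ied_mm = NA_real_) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("rows and cols must be >= 1")
  placements <- as.data.frame(placements)
  need <- c("channel", "row", "col")
  if (!all(need %in% names(placements)))
    stop("placements must have columns: ", paste(need, collapse = ", "))
  placements$channel <- as.character(placements$channel)
  placements$row <- as.integer(placements$row)
  placements$col <- as.integer(placements$col)
  if (anyDuplicated(placements$channel))
    stop("channel placed more than once: ",
         placements$channel[duplicated(placements$channel)][1])
  bad <- placements$row < 1L | placements$row > rows |
    placements$col < 1L | placements$col > cols
  if (any(bad))
    stop("placement out of bounds for channel ",
         placements$channel[which(bad)[1]])
  cell <- paste(placements$row, placements$col)
  if (anyDuplicated(cell)) {
    i <- which(cell == cell[duplicated(cell)][1])
    stop("channels ", paste(placements$channel[i], collapse = " and "),
         " share grid cell (", placements$row[i[1]], ",",
         placements$col[i[1]], ")")
  }
  structure(list(rows = rows, cols = cols, placements = placements,
                 ied_mm = ied_mm),
            class = "electrode_layout")
}

#' Row-major rectangular grid layout
#'
#' Convenience constructor: places `channels` on a `rows x cols` grid in
#' row-major order (channel 1 at (1,1), channel 2 at (1,2), ...).
#'
#' @inheritParams electrode_layout
#' @param channels Character vector of channel labels (length <= rows*cols).
#' @return An [electrode_layout].
#' @export
grid_layout <- function(rows, cols, channels = NULL, ied_mm = NA_real_) {
  if (is.null(channels))
    channels <- sprintf("ch%02d", seq_len(rows * cols))
  n <- length(channels)
  if (n > rows * cols) stop("more channels than grid cells")
  idx <- seq_len(n) - 1L
  electrode_layout(rows, cols,
                   data.frame(channel = channels,
                              row = idx %/% cols + 1L,
                              col = idx %% cols + 1L),
                   ied_mm = ied_mm)
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("electrode_layout: %dx%d grid, %d channels placed",
              x$rows, x$cols, nrow(x$placements)))
  if (!is.na(x$ied_mm)) cat(sprintf(", IED %g mm", x$ied_mm))
  cat("\n")
  g <- matrix(".", x$rows, x$cols)
  g[cbind(x$placements$row, x$placements$col)] <- x$placements$channel
  for (r in seq_len(x$rows)) cat(" ", format(g[r, ], width = 5), "\n")
  invisible(x)
}

#' Number of channels in a layout
#' @param layout An [electrode_layout].
#' @return Integer channel count.
#' @export
n_channels <- function(layout) nrow(layout$placements)
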