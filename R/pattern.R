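#' Simplified 2D spatial activation pattern
#'
#' Arranges one window's per-channel cluster indices on the electrode grid,
#' giving the compact spatial picture of which muscle regions are how
#' active.  Unoccupied grid cells hold `NA`.
#'
#' @param index_row Integer vector of per-channel cluster indices in
#'   `[0, K-1]`, ordered as the layout's placements.
#' @param layout An [electrode_layout].
#' @param K The mixture size the indices refer to.
#' @param time Optional window time (s), carried as metadata.
#' @return An object of class `spatial_pattern` with fields `grid`
#'   (`rows x cols` integer matrix, `NA` = unoccupied), `K`, `layout`,
#'   `time`.
#' @export
to_spatial_pattern <- function(index_row, layout, K, time = NA_real_) {
  index_row <- as.integer(index_row)
  p <- layout$placements
  if (length(index_row) != nrow(p))
    stop("index_row length (", length(index_row),
         ") does not match layout channel count (", nrow(p), ")")
  bad <- index_row < 0L | index_row >= K
  if (any(bad))
    stop("cluster index out of [0, K-1] for channel ",
         p$channel[which(bad)[1]], ": ", index_row[which(bad)[1]])
  grid <- matrix(NA_integer_, layout$rows, layout$cols)
  grid[cbind(p$row, p$col)] <- index_row
  structure(list(grid = grid, K = K, layout = layout, time = time),
            class = "spatial_pattern")
}

#' @export
print.spatial_pattern <- function(x, ...) {
  cat(sprintf("spatial_pattern: %dx%d grid, K = %d",
              nrow(x$grid), ncol(x$grid), x$K))
  if (!is.na(x$time)) cat(sprintf(", t = %.3f s", x$time))
  cat("\n")
  g <- ifelse(is.na(x$grid), ".", as.character(x$grid))
  for (r in seq_len(nrow(g))) cat(" ", format(g[r, ], width = 2), "\n")
  invisible(x)
}

#' Flatten a spatial pattern back to per-channel indices
#'
#' Inverse of [to_spatial_pattern()]: reads the grid through the layout's
#' placements, recovering the per-channel index row.
#'
#' @param pattern A [spatial_pattern].
#' @return Integer vector of per-channel cluster indices.
#' @export
pattern_to_indices <- function(pattern) {
  p <- pattern$layout$placements
  as.integer(pattern$grid[cbind(p$row, p$col)])
}

#' Per-class modal spatial pattern
#'
#' For each channel, the most frequent cluster index over the windows of one
#' class (ties toward the lower index) — the class's characteristic
#' activation pattern.
#'
#' @param indices Integer matrix of cluster indices (windows x channels),
#'   e.g. from [discretize()].
#' @param labels Per-window labels (length `nrow(indices)`).
#' @param class The class whose modal pattern to compute.
#' @return Integer vector of per-channel modal indices.
#' @export
modal_indices <- function(indices, labels, class) {
  sel <- labels == class
  if (!any(sel)) stop("no windows labeled '", class, "'")
  apply(indices[sel, , drop = FALSE], 2, function(col)
    as.integer(names(which.max(table(col)))))
}

#' Rank channels by class discriminability
#'
#' Scores every channel by the mutual information (bits) between its cluster
#' index and the motion label, estimated from the empirical joint
#' frequencies over windows.  A channel whose index never varies carries 0
#' bits; a binary index perfectly aligned with a balanced binary label
#' carries 1 bit.  Useful for selecting an informative electrode subset.
#'
#' @param indices Integer matrix of cluster indices (windows x channels).
#' @param labels Per-window class labels (length `nrow(indices)`); taken
#'   from the `"labels"` attribute of `indices` when omitted.
#' @return A data frame with columns `channel`, `mi_bits`, sorted by
#'   decreasing score (ties keep channel order).
#' @export
select_channels <- function(indices, labels = attr(indices, "labels")) {
  if (is.null(labels)) stop("labels are required")
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) stop("at least two classes are required")
  if (min(table(labels)) < 2)
    stop("each class needs at least two windows")
  chans <- colnames(indices)
  if (is.null(chans)) chans <- sprintf("ch%02d", seq_len(ncol(indices)))
  mi <- vapply(seq_len(ncol(indices)), function(c)
    mutual_information_bits(indices[, c], labels), numeric(1))
  out <- data.frame(channel = chans, mi_bits = mi)
  out[order(-out$mi_bits), , drop = FALSE]
}

# empirical mutual information in bits between two discrete vectors
mutual_information_bits <- function(x, y) {
  j <- table(x, y) / length(x)
  px <- rowSums(j)
  py <- colSums(j)
  nz <- j > 0
  sum(j[nz] * log2(j[nz] / outer(px, py)[nz]))
}
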