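#' Read a multichannel signal file
#'
#' Supported formats: delimited text (header row `time_s, ch.., [label]`,
#' exact) and EDF (European Data Format, 16-bit quantized).  The text
#' format's sampling rate is inferred from the time column, which must be
#' uniform to 1e-6 relative; EDF takes it from the header.  EDF channel
#' units are honored: `uV` is used as-is, `mV` converted to microvolts, any
#' other unit is an error (reported, not guessed).
#'
#' @param path File path.
#' @param format `"text"`, `"edf"`, or `"auto"` (by extension: `.edf` =>
#'   EDF, otherwise text).
#' @return A [semg_record].
#' @export
read_signal <- function(path, format = c("auto", "text", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
    else "text"
  if (format == "edf") return(read_edf(path))
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path)
  if (!"time_s" %in% names(dt))
    stop("missing header: expected a 'time_s' column in ", path)
  t <- dt$time_s
  if (length(t) < 2) stop("need at least two samples to infer sampling rate")
  dt_step <- diff(t)
  step <- stats::median(dt_step)
  bad <- which(abs(dt_step - step) > 1e-6 * step)
  if (length(bad))
    stop("non-uniform sampling: time step at row ", bad[1] + 1L,
         " is ", dt_step[bad[1]], " s (expected ", step, " s)")
  has_label <- "label" %in% names(dt)
  chans <- setdiff(names(dt), c("time_s", "label"))
  semg_record(as.matrix(dt[, chans, with = FALSE]), fs = 1 / step,
              channels = chans,
              labels = if (has_label) dt$label else NULL,
              start_time = t[1])
}

#' Write a multichannel signal file
#'
#' Text is exact (full double precision); EDF quantizes to 16 bits over a
#' physical range of +/- 1.05 x the absolute signal maximum, and drops the
#' label track (EDF carries no per-sample annotations here).
#'
#' @param record A [semg_record]; writing an empty record is refused.
#' @param path Output path.
#' @param format As in [read_signal()].
#' @return `path`, invisibly.
#' @export
write_signal <- function(record, path, format = c("auto", "text", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
    else "text"
  if (nrow(record$samples) == 0)
    stop("refusing to write an empty record")
  if (format == "edf") return(write_edf(record, path))
  dt <- data.table::as.data.table(record$samples)
  data.table::setnames(dt, record$channels)
  dt <- cbind(data.table::data.table(time_s = sample_times(record)), dt)
  if (!is.null(record$labels)) dt$label <- as.character(record$labels)
  data.table::fwrite(dt, path, sep = ",")
  invisible(path)
}

#' Write / read a feature series as delimited text
#'
#' Columns: `time_s`, one per channel, optional `label`.  Window and step
#' sizes travel in a `#window_ms=..,step_ms=..` comment line.
#'
#' @param features A [semg_features].
#' @param path File path.
#' @return `path` (write) or a [semg_features] (read).
#' @export
write_features <- function(features, path) {
  writeLines(sprintf("#window_ms=%g,step_ms=%g",
                     features$window_ms, features$step_ms), path)
  dt <- data.table::as.data.table(features$values)
  data.table::setnames(dt, features$channels)
  dt <- cbind(data.table::data.table(time_s = features$times), dt)
  if (!is.null(features$labels)) dt$label <- as.character(features$labels)
  data.table::fwrite(dt, path, sep = ",", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  meta <- readLines(path, n = 1)
  if (!startsWith(meta, "#"))
    stop("missing metadata line in ", path)
  kv <- strsplit(sub("^#", "", meta), ",")[[1]]
  kv <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  dt <- data.table::fread(path, skip = 1)
  chans <- setdiff(names(dt), c("time_s", "label"))
  semg_features(as.matrix(dt[, chans, with = FALSE]),
                kv[["window_ms"]], kv[["step_ms"]], dt$time_s, chans,
                labels = if ("label" %in% names(dt))
                  factor(dt$label, levels = unique(dt$label)) else NULL)
}

#' Write / read a discretized pattern dataset as delimited text
#'
#' One row per window: `time_s`, per-channel cluster indices, optional
#' `label`; K travels in a comment line.
#'
#' @param indices Integer matrix from [discretize()] (attributes `K`,
#'   `times`, `labels` are serialized alongside).
#' @param path File path.
#' @return `path` (write); for the reader, the index matrix with the
#'   attributes restored.
#' @export
write_patterns <- function(indices, path) {
  K <- attr(indices, "K")
  if (is.null(K)) stop("indices must carry a K attribute")
  writeLines(sprintf("#K=%d", K), path)
  dt <- data.table::as.data.table(indices)
  tm <- attr(indices, "times")
  dt <- cbind(data.table::data.table(
    time_s = if (is.null(tm)) seq_len(nrow(indices)) else tm), dt)
  lb <- attr(indices, "labels")
  if (!is.null(lb)) dt$label <- as.character(lb)
  data.table::fwrite(dt, path, sep = ",", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  meta <- readLines(path, n = 1)
  K <- as.integer(sub("#K=", "", meta, fixed = TRUE))
  dt <- data.table::fread(path, skip = 1)
  chans <- setdiff(names(dt), c("time_s", "label"))
  idx <- as.matrix(dt[, chans, with = FALSE])
  attr(idx, "K") <- K
  attr(idx, "times") <- dt$time_s
  if ("label" %in% names(dt))
    attr(idx, "labels") <- factor(dt$label, levels = unique(dt$label))
  idx
}

#' Serialize / load a fitted mixture as structured text
#'
#' @param model A [gmm1d] fit.
#' @param path File path (YAML).
#' @return `path` (write) or a `gmm1d` (read).
#' @export
write_gmm <- function(model, path) {
  yaml::write_yaml(list(
    type = "gmm1d", K = model$K,
    weights = model$weights, means = model$means,
    variances = model$variances, logLik = model$logLik,
    n = model$n, iterations = model$iterations,
    converged = model$converged, floor_hit = model$floor_hit,
    var_floor = model$var_floor), path,
    precision = 17)
  invisible(path)
}

#' @rdname write_gmm
#' @export
read_gmm <- function(path) {
  y <- yaml::read_yaml(path)
  if (!identical(y$type, "gmm1d")) stop("not a gmm1d file: ", path)
  structure(list(K = as.integer(y$K), weights = as.numeric(y$weights),
                 means = as.numeric(y$means),
                 variances = as.numeric(y$variances),
                 logLik = y$logLik, ll_trace = y$logLik, n = y$n,
                 iterations = y$iterations, converged = y$converged,
                 floor_hit = y$floor_hit, degenerate = FALSE,
                 var_floor = y$var_floor, call = NULL),
            class = "gmm1d")
}

#' Serialize / load an electrode layout as structured text
#'
#' @param layout An [electrode_layout].
#' @param path File path (YAML).
#' @return `path` (write) or an `electrode_layout` (read).
#' @export
write_layout <- function(layout, path) {
  yaml::write_yaml(list(
    rows = layout$rows, cols = layout$cols, ied_mm = layout$ied_mm,
    placements = lapply(seq_len(nrow(layout$placements)), function(i)
      as.list(layout$placements[i, ]))), path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  y <- yaml::read_yaml(path)
  p <- do.call(rbind, lapply(y$placements, as.data.frame))
  electrode_layout(y$rows, y$cols, p,
                   ied_mm = if (is.null(y$ied_mm)) NA_real_ else y$ied_mm)
}

#' Serialize / load a trained pattern classifier as structured text
#'
#' @param model A [train_classifier()] fit.
#' @param path File path (YAML).
#' @return `path` (write) or a `pattern_net` (read).
#' @export
write_classifier <- function(model, path) {
  yaml::write_yaml(list(
    type = "pattern_net", classes = model$classes, K = model$K,
    n_channels = model$n_channels, hidden = model$hidden,
    W1 = as.numeric(model$W1), b1 = model$b1,
    W2 = as.numeric(model$W2), b2 = model$b2,
    loss = model$loss, seed = model$seed, epochs = model$epochs,
    lr = model$lr, batch_size = model$batch_size), path,
    precision = 17)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  y <- yaml::read_yaml(path)
  if (!identical(y$type, "pattern_net"))
    stop("not a pattern_net file: ", path)
  d <- y$n_channels * y$K
  structure(list(
    W1 = matrix(as.numeric(y$W1), d, y$hidden),
    b1 = as.numeric(y$b1),
    W2 = matrix(as.numeric(y$W2), y$hidden, length(y$classes)),
    b2 = as.numeric(y$b2),
    classes = y$classes, K = y$K, n_channels = y$n_channels,
    hidden = y$hidden, loss = as.numeric(y$loss), seed = y$seed,
    epochs = y$epochs, lr = y$lr, batch_size = y$batch_size),
    class = "pattern_net")
}
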