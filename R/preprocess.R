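#' Digital filter specification
#'
#' Describes either a Butterworth bandpass or a second-order IIR power-line
#' notch.  The bandpass defaults mirror a typical sEMG acquisition chain
#' (5-450 Hz); the notch defaults to 60 Hz mains with quality factor 30
#' (3-dB bandwidth `center_hz / quality_factor` = 2 Hz).
#'
#' @param kind `"bandpass"` or `"notch"`.
#' @param low_hz,high_hz Bandpass corner frequencies (Hz).
#' @param center_hz Notch center frequency (Hz).
#' @param quality_factor Notch quality factor (> 0).
#' @param order Butterworth order per edge for the bandpass (default 4); the
#'   notch is always a biquad.
#' @param zero_phase If `TRUE` (default) filtering is forward-backward
#'   (zero phase, offline); if `FALSE` a single causal pass is used, as in a
#'   real-time system.  The two modes are not identical: the causal pass has
#'   group delay and a startup transient.
#'
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "notch"),
                        low_hz = 5, high_hz = 450,
                        center_hz = 60, quality_factor = 30,
                        order = 4, zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (kind == "bandpass") {
    if (!(low_hz > 0 && high_hz > low_hz))
      stop("bandpass requires 0 < low_hz < high_hz")
    if (order < 1) stop("order must be >= 1")
  } else {
    if (center_hz <= 0) stop("center_hz must be > 0")
    if (quality_factor <= 0) stop("quality_factor must be > 0")
  }
  structure(list(kind = kind, low_hz = low_hz, high_hz = high_hz,
                 center_hz = center_hz, quality_factor = quality_factor,
                 order = order, zero_phase = zero_phase),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  if (x$kind == "bandpass")
    cat(sprintf("filter_spec: Butterworth bandpass %g-%g Hz, order %d, %s\n",
                x$low_hz, x$high_hz, x$order,
                if (x$zero_phase) "zero-phase" else "causal"))
  else
    cat(sprintf("filter_spec: IIR notch %g Hz, Q = %g, %s\n",
                x$center_hz, x$quality_factor,
                if (x$zero_phase) "zero-phase" else "causal"))
  invisible(x)
}

# (b, a) coefficients of the designed filter at sampling rate fs
design_coefficients <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$kind == "bandpass") {
    if (spec$high_hz >= nyq)
      stop("bandpass high cutoff (", spec$high_hz,
           " Hz) must be below Nyquist (", nyq, " Hz)")
    bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                         type = "pass")
    list(b = bf$b, a = bf$a)
  } else {
    if (spec$center_hz >= nyq)
      stop("notch center (", spec$center_hz,
           " Hz) must be below Nyquist (", nyq, " Hz)")
    w0 <- 2 * pi * spec$center_hz / fs
    alpha <- sin(w0) / (2 * spec$quality_factor)
    list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
         a = c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha)))
  }
}

apply_filter <- function(record, spec) {
  ba <- design_coefficients(spec, record$fs)
  x <- record$samples
  warmup <- max(3 * (length(ba$a) - 1), 100L)
  if (spec$zero_phase && nrow(x) <= 3 * (length(ba$a) - 1))
    stop("record (", nrow(x), " samples) shorter than the filter warm-up ",
         "length (", 3 * (length(ba$a) - 1) + 1, " samples)")
  y <- x
  for (c in seq_len(ncol(x)))
    y[, c] <- if (spec$zero_phase)
      signal::filtfilt(ba$b, ba$a, x[, c])
    else
      as.numeric(signal::filter(ba$b, ba$a, x[, c]))
  out <- semg_record(y, record$fs, channels = record$channels,
                     labels = record$labels, start_time = record$start_time)
  attr(out, "warmup_samples") <- if (spec$zero_phase) 0L else warmup
  out
}

#' Bandpass filter a recording
#'
#' Applies an order-`order` Butterworth bandpass to every channel
#' independently.  Defaults to the 5-450 Hz band used by sEMG front ends.
#'
#' @param record A [semg_record].
#' @param spec A bandpass [filter_spec]; built from `low_hz`/`high_hz`/
#'   `order`/`zero_phase` when omitted.
#' @param low_hz,high_hz,order,zero_phase See [filter_spec()].
#' @return A filtered [semg_record] of identical shape.  In causal mode the
#'   attribute `warmup_samples` flags the startup-transient region.
#' @export
bandpass <- function(record, spec = NULL, low_hz = 5, high_hz = 450,
                     order = 4, zero_phase = TRUE) {
  if (is.null(spec))
    spec <- filter_spec("bandpass", low_hz = low_hz, high_hz = high_hz,
                        order = order, zero_phase = zero_phase)
  if (spec$kind != "bandpass") stop("spec is not a bandpass filter_spec")
  apply_filter(record, spec)
}

#' Notch filter a recording
#'
#' Applies a biquad notch (default 60 Hz, Q = 30) to every channel to remove
#' power-line interference.  Use `center_hz = 50` for 50 Hz mains.
#'
#' @inheritParams bandpass
#' @param spec A notch [filter_spec]; built from the other arguments when
#'   omitted.
#' @param center_hz,quality_factor,zero_phase See [filter_spec()].
#' @return A filtered [semg_record] of identical shape.
#' @export
notch <- function(record, spec = NULL, center_hz = 60, quality_factor = 30,
                  zero_phase = TRUE) {
  if (is.null(spec))
    spec <- filter_spec("notch", center_hz = center_hz,
                        quality_factor = quality_factor,
                        zero_phase = zero_phase)
  if (spec$kind != "notch") stop("spec is not a notch filter_spec")
  apply_filter(record, spec)
}

#' Analytic frequency response of a designed filter
#'
#' Evaluates the transfer function of the filter that [bandpass()] or
#' [notch()] would apply, at the requested frequencies.  For zero-phase
#' (forward-backward) filtering the reported gain is doubled in dB, since the
#' magnitude response is applied twice.
#'
#' @param spec A [filter_spec].
#' @param fs Sampling rate in Hz.
#' @param freqs Frequencies (Hz) in (0, fs/2) at which to evaluate.
#' @return Numeric vector of gains in dB.
#' @export
frequency_response <- function(spec, fs, freqs) {
  if (any(freqs <= 0 | freqs >= fs / 2))
    stop("freqs must lie strictly inside (0, fs/2)")
  ba <- design_coefficients(spec, fs)
  w <- 2 * pi * freqs / fs
  z <- exp(1i * w)
  H <- vapply(z, function(zi)
    sum(ba$b * zi^-(seq_along(ba$b) - 1)) /
      sum(ba$a * zi^-(seq_along(ba$a) - 1)), complex(1))
  g <- 20 * log10(Mod(H))
  if (spec$zero_phase) 2 * g else g
}
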