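#' Configuration for a synthetic HD-sEMG session
#'
#' Describes a simulated recording session on an electrode grid.  Each motion
#' class assigns every channel a target RMS amplitude (microvolts) for the
#' EMG-like component; on top of that every channel carries an additive white
#' noise floor.  The EMG-like component is Gaussian noise band-limited to
#' `emg_band`, so its amplitude is exactly calibratable: during a steady
#' segment of motion `m`, channel `c` has long-run RMS
#' `sqrt(activation_map[m, c]^2 + noise_floor^2)`.
#'
#' @param classes Character vector of motion names, including a rest class.
#'   The first occurrence order defines the class order used for tie-breaks.
#' @param activation_map Numeric matrix `n_classes x n_channels` of target
#'   RMS amplitudes in microvolts (rows named by class), all `>= 0`.
#' @param layout An [electrode_layout] whose channel count matches
#'   `ncol(activation_map)`.
#' @param schedule Data frame with columns `motion` (class name) and
#'   `duration` (seconds, > 0), executed in order.
#' @param sampling_rate Sampling rate in Hz (default 1000).
#' @param noise_floor Standard deviation of the additive white noise in
#'   microvolts (> 0, default 3).
#' @param emg_band Numeric length-2, spectral band (Hz) of the EMG-like
#'   component (default `c(20, 450)`); must lie inside (0, Nyquist).
#' @param onset_ramp Linear amplitude ramp duration (s) applied at motion
#'   transitions (default 0.1).
#' @param seed Integer seed making the generated session reproducible.
#'
#' @return An object of class `simulation_config`.
#' @seealso [generate_session()], [default_finger_flexion_config()]
#' @export
simulation_config <- function(classes, activation_map, layout, schedule,
                              sampling_rate = 1000, noise_floor = 3,
                              emg_band = c(20, 450), onset_ramp = 0.1,
                              seed = 1L) {
  cfg <- structure(
    list(classes = as.character(classes),
         activation_map = as.matrix(activation_map),
         layout = layout,
         schedule = as.data.frame(schedule),
         sampling_rate = sampling_rate,
         noise_floor = noise_floor,
         emg_band = as.numeric(emg_band),
         onset_ramp = onset_ramp,
         seed = as.integer(seed)),
    class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  am <- cfg$activation_map
  if (is.null(rownames(am)) || !setequal(rownames(am), cfg$classes))
    stop("activation_map rows must be named by the classes")
  if (any(am < 0)) stop("activation_map: amplitudes must be >= 0")
  if (!is.null(cfg$layout) && n_channels(cfg$layout) != ncol(am))
    stop("layout places ", n_channels(cfg$layout),
         " channels but activation_map has ", ncol(am))
  if (cfg$noise_floor <= 0) stop("noise_floor must be > 0")
  if (nrow(cfg$schedule) == 0) stop("schedule is empty")
  if (!all(c("motion", "duration") %in% names(cfg$schedule)))
    stop("schedule needs columns 'motion' and 'duration'")
  if (any(cfg$schedule$duration <= 0))
    stop("schedule: durations must be > 0 (row ",
         which(cfg$schedule$duration <= 0)[1], ")")
  unknown <- setdiff(cfg$schedule$motion, cfg$classes)
  if (length(unknown))
    stop("scheduled motion not in classes: ", unknown[1])
  nyq <- cfg$sampling_rate / 2
  if (length(cfg$emg_band) != 2 || cfg$emg_band[1] <= 0 ||
      cfg$emg_band[2] <= cfg$emg_band[1] || cfg$emg_band[2] >= nyq)
    stop("emg_band must satisfy 0 < low < high < sampling_rate/2")
  if (cfg$onset_ramp < 0) stop("onset_ramp must be >= 0")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation_config: %d channels, %d classes, %g Hz, %.1f s\n",
              ncol(x$activation_map), length(x$classes), x$sampling_rate,
              sum(x$schedule$duration)))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat(sprintf("  noise floor %g uV, EMG band %g-%g Hz, ramp %g s, seed %d\n",
              x$noise_floor, x$emg_band[1], x$emg_band[2], x$onset_ramp,
              x$seed))
  invisible(x)
}

# Unit-RMS band-limited Gaussian carrier of length n.  Forward-backward
# order-4 Butterworth confines the power to `band`; the steady-state region
# (edges excluded) is renormalized to RMS 1 so that multiplying by a gives an
# EMG-like component of RMS a.
emg_carrier <- function(n, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  e <- signal::filtfilt(bf, stats::rnorm(n))
  edge <- min(max(100L, round(fs / 2)), n %/% 4)
  core <- if (n > 2 * edge) e[(edge + 1):(n - edge)] else e
  e / sqrt(mean(core^2))
}

#' Generate a labeled synthetic HD-sEMG session
#'
#' Renders the session described by a [simulation_config].  For channel `c`
#' during motion `m` the signal is `x_c(t) = a_c(t) * e_c(t) + n_c(t)`: `e_c`
#' is unit-RMS Gaussian noise band-limited to `emg_band`, `a_c(t)` the target
#' amplitude of the scheduled motion (linearly ramped over `onset_ramp`
#' seconds at transitions), and `n_c` white Gaussian noise with sd
#' `noise_floor`.  All components are independent across channels.  The same
#' configuration (including seed) always produces bit-identical output.
#'
#' @param config A [simulation_config].
#' @return A [semg_record] with per-sample motion labels.
#' @export
generate_session <- function(config) {
  validate_simulation_config(config)
  fs <- config$sampling_rate
  seg_n <- round(config$schedule$duration * fs)
  n <- sum(seg_n)
  nc <- ncol(config$activation_map)
  labels <- rep(config$schedule$motion, seg_n)

  # per-channel amplitude target at every sample, then linear onset ramps
  amp <- config$activation_map[labels, , drop = FALSE]
  ramp_n <- round(config$onset_ramp * fs)
  if (ramp_n > 1) {
    starts <- cumsum(c(1, seg_n))[seq_along(seg_n)]
    for (s in starts[-1]) {
      k <- min(ramp_n, n - s + 1L)
      w <- seq_len(k) / k
      prev <- amp[s - 1L, ]
      for (j in seq_len(k))
        amp[s + j - 1L, ] <- prev + w[j] * (amp[s + j - 1L, ] - prev)
    }
  }

  set.seed(config$seed)
  x <- matrix(0, n, nc)
  for (c in seq_len(nc))
    x[, c] <- amp[, c] * emg_carrier(n, fs, config$emg_band) +
      stats::rnorm(n, sd = config$noise_floor)

  semg_record(x, fs, channels = config$layout$placements$channel,
              labels = factor(labels, levels = config$classes))
}

#' Default synthetic finger-flexion session
#'
#' A 16-channel, 4x4-grid session with six classes (rest plus five
#' single-finger flexions) whose spatial activation structure mimics an
#' HD-sEMG array on the forearm flexor group: channels 1, 4 and 8 are active
#' during every flexion, channel 5 is active only during middle-finger
#' flexion, one further channel is selective for each flexion, channels
#' 9-13 are each shared by two adjacent flexions, and channels 14-16 carry
#' weak activity common to all flexions.  The rest class has all
#' activations at zero.  Any two flexions differ by at least 50 microvolts
#' (>> 3x the 3 microvolt noise floor) in at least one channel, so the five
#' flexions are mutually distinguishable by spatial pattern.
#'
#' @param seed Integer seed for the generated session.
#' @param seconds_per_flexion Duration of each flexion segment (s).
#' @param rest_between Duration of rest segments between flexions (s).
#' @param repetitions How many times the five-flexion sequence is repeated;
#'   with 2 (default) the session supports a clean block-wise train/test
#'   split at its midpoint.
#' @param noise_floor Additive white-noise sd in microvolts.
#' @return A [simulation_config].
#' @export
default_finger_flexion_config <- function(seed = 1L, seconds_per_flexion = 6,
                                          rest_between = 2, repetitions = 2,
                                          noise_floor = 3) {
  classes <- c("rest", "thumb", "index", "middle", "ring", "little")
  flex <- classes[-1]
  am <- matrix(0, length(classes), 16,
               dimnames = list(classes, sprintf("ch%02d", 1:16)))
  am[flex, c(1, 4, 8)] <- 60            # common flexor channels
  dedicated <- c(thumb = 2, index = 3, middle = 5, ring = 6, little = 7)
  for (m in flex) am[m, dedicated[[m]]] <- if (m == "middle") 80 else 70
  # channels 9-13: each shared by two adjacent flexions, so channel 5 stays
  # the only middle-selective channel
  for (j in seq_along(flex)) {
    am[flex[j], 8 + j] <- 50
    am[flex[j %% 5 + 1], 8 + j] <- 50
  }
  am[flex, 14:16] <- 20                 # weak common activity

  sched <- data.frame(motion = "rest", duration = rest_between)
  for (r in seq_len(repetitions))
    for (m in flex)
      sched <- rbind(sched,
                     data.frame(motion = c(m, "rest"),
                                duration = c(seconds_per_flexion,
                                             rest_between)))
  simulation_config(classes = classes, activation_map = am,
                    layout = grid_layout(4, 4),
                    schedule = sched, sampling_rate = 1000,
                    noise_floor = noise_floor, emg_band = c(20, 450),
                    onset_ramp = 0.1, seed = seed)
}
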