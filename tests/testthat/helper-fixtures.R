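# shared fixture builders; everything is generated in code

# pure sine recording (amplitude in uV)
sine_record <- function(freq, amp, fs = 1000, dur = 2, channels = 1) {
  t <- (seq_len(dur * fs) - 1) / fs
  semg_record(matrix(rep(amp * sin(2 * pi * freq * t), channels),
                     ncol = channels), fs)
}

# small two-motion session with strong separation (plus rest)
two_motion_config <- function(seed = 1, dur = 3, reps = 1) {
  classes <- c("rest", "close", "pinch")
  am <- matrix(0, 3, 4, dimnames = list(classes, NULL))
  am["close", ] <- c(60, 60, 0, 0)
  am["pinch", ] <- c(0, 60, 60, 0)
  simulation_config(
    classes = classes, activation_map = am, layout = grid_layout(2, 2),
    schedule = data.frame(
      motion = rep(c("rest", "close", "rest", "pinch"), reps),
      duration = rep(c(1, dur, 1, dur), reps)),
    noise_floor = 3, seed = seed)
}

# steady-state amplitude of a (possibly transient-laden) filtered sinusoid
steady_amplitude <- function(x, fs, trim_s = 0.5) {
  n <- length(x)
  core <- x[(trim_s * fs):(n - trim_s * fs)]
  sqrt(2 * mean(core^2))
}
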