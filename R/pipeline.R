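#' Block-wise train/test split of a window sequence
#'
#' Splits windows at a time point into a training block (before) and a test
#' block (after), dropping a guard interval around the split so that no RMS
#' window overlaps both sides.  Block-wise (rather than random per-window)
#' splitting avoids leakage between overlapping windows.
#'
#' @param times Window end times (s).
#' @param frac Fraction of the total time span used for training
#'   (default 0.5).
#' @param guard_s Guard interval excluded on both sides of the split
#'   (default 0.25 s, comfortably above the default 200 ms window).
#' @return List with integer index vectors `train` and `test`.
#' @export
block_split <- function(times, frac = 0.5, guard_s = 0.25) {
  cut <- min(times) + frac * (max(times) - min(times))
  list(train = which(times <= cut - guard_s),
       test = which(times >= cut + guard_s))
}

#' Steady-state window mask
#'
#' Flags windows lying entirely inside one scheduled segment, at least
#' `margin_s` away from every label transition — the windows on which a
#' classifier's steady-state behavior is judged (transition windows mix two
#' motions and have no single correct label).
#'
#' @param labels Per-window labels.
#' @param times Window end times (s).
#' @param margin_s Distance to the nearest transition (default 0.3 s:
#'   window length plus onset ramp).
#' @return Logical vector.
#' @export
steady_mask <- function(labels, times, margin_s = 0.3) {
  changes <- which(diff(as.integer(as.factor(labels))) != 0)
  if (!length(changes)) return(rep(TRUE, length(labels)))
  tchg <- times[changes]
  vapply(times, function(t) all(abs(t - tchg) >= margin_s), logical(1))
}

#' Run the full HD-sEMG analysis pipeline
#'
#' Executes simulate -> filter -> RMS features -> pooled GMM -> discretize ->
#' train classifier -> majority vote -> evaluate, writing every intermediate
#' artifact plus a manifest to `out_dir`.  Identical configuration and seed
#' reproduce byte-identical feature, pattern and report files.
#'
#' @param config A list (or path to a YAML file) with optional sections:
#'   `simulate` (arguments of [default_finger_flexion_config()]), `signal`
#'   (path of an existing signal file, used instead of simulation),
#'   `preprocess` (`bandpass_low`, `bandpass_high`, `bandpass_order`,
#'   `notch_hz` or `NULL` to skip, `notch_q`, `zero_phase`), `features`
#'   (`window_ms`, `step_ms`, `smooth_span` or 0), `gmm` (`K`, `restarts`),
#'   `split` (`frac`, `guard_s`), `classifier` (`hidden`, `epochs`, `lr`,
#'   `batch_size`), `vote` (`span`).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return Invisibly, a list with the in-memory artifacts (`record`,
#'   `features`, `model`, `indices`, `classifier`, `evaluation`,
#'   `evaluation_vote`, `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- function(section, key, default) {
    v <- config[[section]][[key]]
    if (is.null(v)) default else v
  }
  seed <- as.integer(seed)
  paths <- list()

  # --- simulate or load -----------------------------------------------
  if (!is.null(config$signal)) {
    record <- read_signal(config$signal)
  } else {
    cfg <- default_finger_flexion_config(
      seed = seed,
      seconds_per_flexion = g("simulate", "seconds_per_flexion", 6),
      rest_between = g("simulate", "rest_between", 2),
      repetitions = g("simulate", "repetitions", 2),
      noise_floor = g("simulate", "noise_floor", 3))
    record <- generate_session(cfg)
    paths$signal <- file.path(out_dir, "signal.csv")
    write_signal(record, paths$signal)
  }

  # --- preprocess ------------------------------------------------------
  zero_phase <- isTRUE(g("preprocess", "zero_phase", TRUE))
  rec_f <- bandpass(record,
                    low_hz = g("preprocess", "bandpass_low", 5),
                    high_hz = g("preprocess", "bandpass_high", 450),
                    order = g("preprocess", "bandpass_order", 4),
                    zero_phase = zero_phase)
  notch_hz <- g("preprocess", "notch_hz", 60)
  if (!is.null(notch_hz) && notch_hz > 0)
    rec_f <- notch(rec_f, center_hz = notch_hz,
                   quality_factor = g("preprocess", "notch_q", 30),
                   zero_phase = zero_phase)

  # --- features --------------------------------------------------------
  feats <- sliding_rms(rec_f,
                       window_ms = g("features", "window_ms", 200),
                       step_ms = g("features", "step_ms", 5))
  smooth <- g("features", "smooth_span", 0)
  if (smooth > 1) feats <- moving_average(feats, smooth)
  paths$features <- file.path(out_dir, "features.csv")
  write_features(feats, paths$features)

  # --- pooled GMM + discretization ------------------------------------
  model <- fit_gmm(feats, K = g("gmm", "K", 10),
                   stride = g("gmm", "fit_stride", 4),
                   restarts = g("gmm", "restarts", 0), seed = seed + 1L)
  paths$model <- file.path(out_dir, "gmm.yaml")
  write_gmm(model, paths$model)
  idx <- discretize(feats, model)
  paths$patterns <- file.path(out_dir, "patterns.csv")
  write_patterns(idx, paths$patterns)

  # --- classifier ------------------------------------------------------
  sp <- block_split(feats$times, frac = g("split", "frac", 0.5),
                    guard_s = g("split", "guard_s", 0.25))
  clf <- train_classifier(idx[sp$train, , drop = FALSE],
                          labels = droplevels(feats$labels[sp$train]),
                          K = model$K,
                          hidden = g("classifier", "hidden", 20),
                          epochs = g("classifier", "epochs", 60),
                          lr = g("classifier", "lr", 0.2),
                          batch_size = g("classifier", "batch_size", 64),
                          seed = seed + 2L)
  paths$classifier <- file.path(out_dir, "classifier.yaml")
  write_classifier(clf, paths$classifier)

  # --- evaluation ------------------------------------------------------
  truth <- factor(as.character(feats$labels[sp$test]), levels = clf$classes)
  pred <- predict(clf, idx[sp$test, , drop = FALSE])
  ev <- evaluate(truth, pred, classes = clf$classes)
  span <- g("vote", "span", 41)
  pred_v <- majority_vote(pred, span)
  ev_v <- evaluate(truth, pred_v, classes = clf$classes)

  paths$report <- file.path(out_dir, "report.yaml")
  yaml::write_yaml(list(
    accuracy_raw = ev$accuracy, accuracy_vote = ev_v$accuracy,
    n_train = length(sp$train), n_test = length(sp$test),
    vote_span = span,
    confusion_raw = unclass(as.matrix(ev$confusion)),
    confusion_vote = unclass(as.matrix(ev_v$confusion))),
    paths$report, precision = 17)

  # --- manifest --------------------------------------------------------
  manifest <- list(
    package = "semgrid",
    version = as.character(utils::packageVersion("semgrid")),
    seed = seed,
    stage_seeds = list(simulate = seed, gmm = seed + 1L,
                       classifier = seed + 2L),
    config = config,
    artifacts = lapply(paths, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(record = record, features = feats, model = model,
                 indices = idx, classifier = clf, split = sp,
                 evaluation = ev, evaluation_vote = ev_v,
                 manifest = manifest, paths = paths))
}
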