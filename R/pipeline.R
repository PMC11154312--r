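# End-to-end orchestration: configuration validation, the session pipeline
# from raw trace + facial stream to per-window fused fatigue decisions, and
# deterministic report output.

#' Default pipeline configuration
#'
#' Nested configuration covering every stage. All values can be overridden
#' through [validate_config()].
#'
#' @return a list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    fs_hz = 30,
    fps = 20,
    window_s = 60,
    seed = 1L,
    out_dir = NULL,
    ssa = list(M = 30L, passband = c(0.8, 4), ma_window_s = 1, taps_s = 3),
    detector = list(integration_window_s = 0.15, refractory_s = 0.2,
                    searchback_factor = 1.66, init_s = 3),
    spectral = list(fs = 4, L = 128L, window = "hamming",
                    overlap = "quarter-step",
                    lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40)),
    facial = list(window_frames = 1200L, eye_threshold = 0.5,
                  mouth_threshold = 0.5, min_yawn_run = 1L, eye_scale = 0.6),
    models = list(hidden_size = 8L, epochs_cnn = 20L, epochs_bilstm = 30L,
                  n_per_class = 60L, n_sessions = 30L)
  ), class = "pipeline_config")
}

merge_config <- function(base, user, path = character(0)) {
  for (nm in names(user)) {
    full <- paste(c(path, nm), collapse = "$")
    if (!nm %in% names(base))
      stopf("unknown configuration key '%s'", full)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]]))
        stopf("configuration key '%s' must be a list", full)
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], c(path, nm))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate and complete a pipeline configuration
#'
#' Accepts a (possibly partial) configuration list or a YAML file path,
#' fills every missing field from [default_config()], rejects unknown keys,
#' and checks the cross-field invariants, naming the offending key in every
#' error.
#'
#' @param config partial configuration list, a YAML path, or `NULL` for the
#'   defaults.
#' @return a validated `pipeline_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (inherits(config, "pipeline_config")) config <- unclass(config)
  cfg <- merge_config(unclass(default_config()), config %||% list())
  check_number(cfg$fs_hz, "fs_hz", lower = 1e-9)
  check_number(cfg$fps, "fps", lower = 1e-9)
  check_number(cfg$window_s, "window_s", lower = 1)
  pb <- cfg$ssa$passband
  if (!(pb[1] > 0 && pb[1] < pb[2]))
    stopf("ssa$passband must be ascending and positive")
  if (pb[2] >= cfg$fs_hz / 2)
    stopf("ssa$passband high edge (%g Hz) must be below the Nyquist frequency (%g Hz)",
          pb[2], cfg$fs_hz / 2)
  if (cfg$ssa$M < 2) stopf("ssa$M must be at least 2")
  check_number(cfg$detector$refractory_s, "detector$refractory_s", lower = 1e-9)
  check_number(cfg$detector$integration_window_s,
               "detector$integration_window_s", lower = 1e-9)
  sc <- spectral_config(fs = cfg$spectral$fs, L = cfg$spectral$L,
                        window = cfg$spectral$window,
                        overlap = cfg$spectral$overlap,
                        lf_band = cfg$spectral$lf_band,
                        hf_band = cfg$spectral$hf_band)
  check_number(cfg$facial$window_frames, "facial$window_frames", lower = 1)
  if (abs(cfg$facial$window_frames - cfg$fps * cfg$window_s) > 1e-9)
    stopf("facial$window_frames (%d) must equal fps * window_s (%g)",
          cfg$facial$window_frames, cfg$fps * cfg$window_s)
  attr(cfg, "spectral_config") <- sc
  structure(cfg, class = "pipeline_config")
}

#' Write a configuration to YAML
#'
#' @param config a `pipeline_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(validate_config(config)), path)
  invisible(path)
}

#' Run the full fatigue-detection pipeline on one session
#'
#' Orchestrates every stage: SSA denoising of the raw trace, beat detection,
#' per-window HRV features, per-window PERCLOS/yawn rates from the facial
#' stream, the two CNN inputs, and (when a model stack is supplied) the
#' fused BiLSTM decision per window. The run is deterministic for a fixed
#' configuration; when `config$out_dir` is set, the report is written as
#' `report.json` and `report.csv` stamped with the configuration hash.
#'
#' @param input a `sim_session` object or a session directory (see
#'   [write_session()] / [read_session()]).
#' @param config a [validate_config()]-acceptable configuration.
#' @param models optional [train_fatigue_models()] stack; without it, only
#'   features are reported.
#' @return object of class `session_report`: `windows` (a data.frame with
#'   one row per complete window), `metadata`, and `beats`.
#' @export
run_pipeline <- function(input, config = NULL, models = NULL) {
  cfg <- validate_config(config)
  session <- if (inherits(input, "sim_session")) input else read_session(input)
  if (is.null(session$trace) || nrow(session$trace) == 0L)
    stopf("session has no trace data")
  sc <- attr(cfg, "spectral_config")

  stage <- function(what, win, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stopf("stage '%s'%s failed: %s", what,
            if (is.na(win)) "" else sprintf(" (window %d)", win),
            conditionMessage(e)))
    message(sprintf("[%s%s] %.2f s", what,
                    if (is.na(win)) "" else sprintf(" w%d", win),
                    proc.time()[["elapsed"]] - t0))
    out
  }

  den <- stage("ssa-denoise", NA, ssa_denoise(
    session$trace$value, cfg$fs_hz, M = cfg$ssa$M,
    passband = cfg$ssa$passband, ma_window_s = cfg$ssa$ma_window_s,
    taps_s = cfg$ssa$taps_s))
  beats <- stage("detect-beats", NA, detect_beats(
    den$filtered, cfg$fs_hz,
    integration_window_s = cfg$detector$integration_window_s,
    refractory_s = cfg$detector$refractory_s,
    searchback_factor = cfg$detector$searchback_factor,
    init_s = cfg$detector$init_s))

  duration <- nrow(session$trace) / cfg$fs_hz
  n_win <- floor(duration / cfg$window_s)
  if (n_win < 1L) stopf("session shorter than one %g s window", cfg$window_s)

  rows <- vector("list", n_win)
  hr_probs <- matrix(NA_real_, n_win, 2L)
  face_probs <- matrix(NA_real_, n_win, 2L)
  for (w in seq_len(n_win)) {
    t0 <- (w - 1L) * cfg$window_s
    t1 <- w * cfg$window_s
    bt <- beats$peak_times[beats$peak_times >= t0 & beats$peak_times < t1]
    feats <- stage("hrv", w, {
      if (length(bt) < 6L) stopf("only %d beats in window", length(bt))
      dd <- diff(bt)
      td <- hrv_time_domain(dd)
      tach <- build_tachogram(bt, dd, fs_out = sc$fs)
      bp <- band_powers(welch_psd(tach$y, sc), sc)
      c(td, bp)
    })
    fr <- session$frames[session$frames$time_s >= t0 - 1e-9 &
                           session$frames$time_s < t1 - 1e-9, ]
    face <- stage("face-rates", w, {
      states <- classify_states(fr,
                                eye_threshold = cfg$facial$eye_threshold,
                                mouth_threshold = cfg$facial$mouth_threshold,
                                min_yawn_run = cfg$facial$min_yawn_run)
      window_rates(states, cfg$facial$window_frames)
    })
    if (!is.null(models)) {
      hr_x <- stage("hr-input", w, build_hr_input(
        hr_feature_track(bt, cfg = spectral_config(fs = sc$fs, L = 128L))))
      face_x <- stage("face-input", w,
                      build_face_input(fr$eye_openness, fr$mouth_openness))
      hr_probs[w, ] <- predict(models$hr, hr_x)
      face_probs[w, ] <- predict(models$face, face_x)
    }
    rows[[w]] <- data.frame(
      window = w, t_start_s = t0, t_end_s = t1, n_beats = length(bt),
      mean_s = feats$mean_s, sd_s = feats$sd_s,
      lf = feats$lf, hf = feats$hf, lf_hf = feats$lf_hf,
      perclos = face$perclos, yawn_rate = face$yawn_rate)
  }
  windows <- do.call(rbind, rows)
  if (!is.null(models)) {
    fused <- predict(models$fusion, cbind(hr_probs, face_probs))
    windows$p_fatigue_hr <- hr_probs[, 2]
    windows$p_fatigue_face <- face_probs[, 2]
    windows$p_fatigue_fused <- fused[, 2]
    windows$decision <- ifelse(fused[, 2] >= 0.5, "fatigued", "awake")
  }
  hash_cfg <- unclass(cfg)
  hash_cfg$out_dir <- NULL   # the output location is not part of the analysis
  meta <- list(config_hash = object_hash(hash_cfg),
               seed = cfg$seed,
               version = as.character(utils::packageVersion("rppgfatigue")),
               n_windows = n_win,
               ssa_components = den$components,
               n_beats = length(beats$peak_times))
  report <- structure(list(windows = windows, metadata = meta, beats = beats),
                      class = "session_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Write a session report to disk
#'
#' Emits `report.json` (windows + metadata) and `report.csv` (windows
#' only); both are byte-stable across identical runs.
#'
#' @param report a `session_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "session_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(metadata = report$metadata,
                            windows = report$windows),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(report$windows, file.path(dir, "report.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("Session report: %d windows, %d beats (config %s)\n",
              x$metadata$n_windows, x$metadata$n_beats,
              x$metadata$config_hash))
  cols <- intersect(c("window", "mean_s", "sd_s", "lf_hf", "perclos",
                      "yawn_rate", "p_fatigue_fused", "decision"),
                    names(x$windows))
  print(x$windows[, cols], digits = 3, row.names = FALSE)
  invisible(x)
}
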