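#' Configuration for a simulated RR (inter-beat interval) series
#'
#' The simulated tachogram is the sum of a constant base interval, two
#' sinusoidal modulations (one in the sympathetic low-frequency band, one in
#' the vagal high-frequency band) and Gaussian jitter. The analytic LF/HF
#' power ratio of the two sinusoids, `lf_amp_s^2 / hf_amp_s^2`, is recorded
#' as ground truth.
#'
#' @param duration_s total simulated duration in seconds.
#' @param mean_hr_bpm mean heart rate, beats per minute (30-180).
#' @param lf_amp_s,hf_amp_s modulation amplitudes of the interval series, in
#'   seconds.
#' @param lf_freq_hz,hf_freq_hz modulation frequencies in Hz; the LF
#'   frequency must be below the HF frequency.
#' @param jitter_sd_s standard deviation of Gaussian interval jitter, seconds.
#' @param seed integer seed for the jitter stream.
#' @return a list of class `rr_sim_config`.
#' @export
rr_sim_config <- function(duration_s = 300, mean_hr_bpm = 60,
                          lf_amp_s = 0.03, hf_amp_s = 0.03,
                          lf_freq_hz = 0.1, hf_freq_hz = 0.25,
                          jitter_sd_s = 0, seed = 1L) {
  check_number(duration_s, "duration_s", lower = 1e-9)
  check_number(mean_hr_bpm, "mean_hr_bpm", lower = 30, upper = 180)
  check_number(lf_amp_s, "lf_amp_s", lower = 0)
  check_number(hf_amp_s, "hf_amp_s", lower = 0)
  check_number(lf_freq_hz, "lf_freq_hz", lower = 0)
  check_number(hf_freq_hz, "hf_freq_hz", lower = 0)
  check_number(jitter_sd_s, "jitter_sd_s", lower = 0)
  if (lf_freq_hz >= hf_freq_hz)
    stopf("lf_freq_hz (%g) must be below hf_freq_hz (%g)", lf_freq_hz, hf_freq_hz)
  structure(list(duration_s = duration_s, mean_hr_bpm = mean_hr_bpm,
                 lf_amp_s = lf_amp_s, hf_amp_s = hf_amp_s,
                 lf_freq_hz = lf_freq_hz, hf_freq_hz = hf_freq_hz,
                 jitter_sd_s = jitter_sd_s, seed = as.integer(seed)),
            class = "rr_sim_config")
}

#' Simulate an RR interval series with known LF/HF structure
#'
#' Intervals are generated sequentially: the i-th interval equals the base
#' interval `60/mean_hr_bpm` plus the two sinusoidal modulations evaluated at
#' the cumulative beat time, plus Gaussian jitter. Beat times are the
#' cumulative sums of the intervals, with the first beat at time 0, so
#' `diff(beat_times)` reproduces the interval sequence exactly.
#'
#' @param cfg an [rr_sim_config()].
#' @return a list with `intervals` (seconds), `beat_times` (seconds, first at
#'   0) and `truth`, a ground-truth list carrying `true_lf_over_hf` (the
#'   analytic sinusoid power ratio; `NA` when both amplitudes are zero).
#' @export
simulate_rr_series <- function(cfg) {
  stopifnot(inherits(cfg, "rr_sim_config"))
  base <- 60 / cfg$mean_hr_bpm
  with_seed(cfg$seed, {
    intervals <- numeric(0)
    t_cur <- 0
    repeat {
      iv <- base +
        cfg$lf_amp_s * sin(2 * pi * cfg$lf_freq_hz * t_cur) +
        cfg$hf_amp_s * sin(2 * pi * cfg$hf_freq_hz * t_cur) +
        (if (cfg$jitter_sd_s > 0) stats::rnorm(1, 0, cfg$jitter_sd_s) else 0)
      if (iv <= 0.05)  # 0.05 s = 1200 bpm: no physiological interval is shorter
        stopf("configuration produced a non-positive or implausibly small interval (%.4f s) at t=%.2f s; reduce amplitudes or jitter", iv, t_cur)
      if (t_cur + iv > cfg$duration_s + 1e-12) break
      intervals <- c(intervals, iv)
      t_cur <- t_cur + iv
    }
    if (length(intervals) < 2L)
      stopf("duration_s too short: only %d interval(s) generated", length(intervals))
    ratio <- if (cfg$hf_amp_s == 0 && cfg$lf_amp_s == 0) NA_real_
             else if (cfg$hf_amp_s == 0) Inf
             else (cfg$lf_amp_s / cfg$hf_amp_s)^2
    beat_times <- c(0, cumsum(intervals))
    list(intervals = intervals,
         beat_times = beat_times,
         truth = list(beat_times = beat_times,
                      true_intervals = intervals,
                      true_lf_over_hf = ratio,
                      mean_hr_bpm = cfg$mean_hr_bpm,
                      seed = cfg$seed))
  })
}

#' Configuration for rendering a pulse waveform from beat times
#'
#' @param fs_hz sampling rate in samples per second; must exceed twice the
#'   4 Hz top of the cardiac passband.
#' @param pulse_width_s width of the raised-cosine pulse, seconds.
#' @param noise_sd standard deviation of additive Gaussian noise, intensity
#'   units.
#' @param drift_amp amplitude of an additive respiratory-band drift sinusoid.
#' @param drift_freq_hz drift frequency in Hz (default 0.2, typical
#'   respiration).
#' @param seed integer seed for the noise stream.
#' @return a list of class `pulse_sim_config`.
#' @export
pulse_sim_config <- function(fs_hz = 30, pulse_width_s = 0.5, noise_sd = 0,
                             drift_amp = 0, drift_freq_hz = 0.2, seed = 1L) {
  check_number(fs_hz, "fs_hz", lower = 8 + 1e-12)
  check_number(pulse_width_s, "pulse_width_s", lower = 1e-9)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(drift_amp, "drift_amp", lower = 0)
  check_number(drift_freq_hz, "drift_freq_hz", lower = 0)
  structure(list(fs_hz = fs_hz, pulse_width_s = pulse_width_s,
                 noise_sd = noise_sd, drift_amp = drift_amp,
                 drift_freq_hz = drift_freq_hz, seed = as.integer(seed)),
            class = "pulse_sim_config")
}

#' Render a sampled pulse waveform from beat times
#'
#' Each beat contributes one raised-cosine pulse of width `pulse_width_s`
#' centred at its beat time; a drift sinusoid and Gaussian noise are added on
#' top. Sample k (0-based) is taken at time k / fs, so with zero noise the
#' argmax of an isolated pulse falls within half a sample of its beat time.
#'
#' @param beat_times ascending beat times in seconds (may be empty).
#' @param cfg a [pulse_sim_config()].
#' @param duration_s trace duration; defaults to the last beat plus half a
#'   pulse width.
#' @param amplitudes per-beat pulse amplitudes, recycled (default 1).
#' @return numeric intensity trace of length `ceiling(duration_s * fs_hz)`.
#' @export
render_pulse_waveform <- function(beat_times, cfg, duration_s = NULL,
                                  amplitudes = 1) {
  stopifnot(inherits(cfg, "pulse_sim_config"))
  if (length(beat_times) && any(diff(beat_times) <= 0))
    stopf("beat_times must be strictly ascending")
  if (is.null(duration_s))
    duration_s <- if (length(beat_times)) max(beat_times) + cfg$pulse_width_s / 2 else 1
  n <- as.integer(ceiling(duration_s * cfg$fs_hz))
  tt <- (seq_len(n) - 1) / cfg$fs_hz
  x <- numeric(n)
  if (length(beat_times)) {
    amplitudes <- rep_len(amplitudes, length(beat_times))
    if (any(diff(beat_times) < cfg$pulse_width_s))
      warnf("beat intervals shorter than pulse_width_s (%.3f s): pulses overlap", cfg$pulse_width_s)
    half <- cfg$pulse_width_s / 2
    for (i in seq_along(beat_times)) {
      sel <- which(abs(tt - beat_times[i]) <= half)
      if (length(sel))
        x[sel] <- x[sel] + amplitudes[i] *
          0.5 * (1 + cos(pi * (tt[sel] - beat_times[i]) / half))
    }
  }
  if (cfg$drift_amp > 0)
    x <- x + cfg$drift_amp * sin(2 * pi * cfg$drift_freq_hz * tt)
  if (cfg$noise_sd > 0)
    x <- x + with_seed(cfg$seed, stats::rnorm(n, 0, cfg$noise_sd))
  x
}

#' Configuration for a simulated eye/mouth state stream
#'
#' @param fps frames per second (default 20, matching 1200 frames per 60 s
#'   window).
#' @param window_s window duration in seconds; `fps * window_s` must be an
#'   integer.
#' @param closed_fraction fraction of frames with closed eyes, in \[0, 1\].
#' @param yawn_fraction fraction of frames inside yawns, in \[0, 1\].
#' @param blink_mean_dur_s mean duration of one closed-eye run, seconds.
#' @param yawn_mean_dur_s mean duration of one yawn run, seconds.
#' @param score_noise_sd Gaussian noise on the openness scores.
#' @param seed integer seed.
#' @return a list of class `eye_state_sim_config`.
#' @export
eye_state_sim_config <- function(fps = 20, window_s = 60,
                                 closed_fraction = 0.1, yawn_fraction = 0,
                                 blink_mean_dur_s = 0.3, yawn_mean_dur_s = 4,
                                 score_noise_sd = 0, seed = 1L) {
  check_number(fps, "fps", lower = 1)
  check_number(window_s, "window_s", lower = 1e-9)
  n <- fps * window_s
  if (abs(n - round(n)) > 1e-9)
    stopf("fps * window_s must be an integer number of frames (got %g)", n)
  check_number(closed_fraction, "closed_fraction", lower = 0, upper = 1)
  check_number(yawn_fraction, "yawn_fraction", lower = 0, upper = 1)
  check_number(blink_mean_dur_s, "blink_mean_dur_s", lower = 1e-9)
  check_number(yawn_mean_dur_s, "yawn_mean_dur_s", lower = 1e-9)
  check_number(score_noise_sd, "score_noise_sd", lower = 0)
  structure(list(fps = fps, window_s = window_s,
                 closed_fraction = closed_fraction,
                 yawn_fraction = yawn_fraction,
                 blink_mean_dur_s = blink_mean_dur_s,
                 yawn_mean_dur_s = yawn_mean_dur_s,
                 score_noise_sd = score_noise_sd, seed = as.integer(seed)),
            class = "eye_state_sim_config")
}

# Place exactly n_on frames in runs with approximately exponential run
# lengths across n frames. Returns a logical vector with sum == n_on.
place_runs <- function(n, n_on, mean_run) {
  state <- logical(n)
  if (n_on == 0) return(state)
  if (n_on > n) stopf("cannot place %d active frames in %d frames", n_on, n)
  runs <- integer(0)
  left <- n_on
  while (left > 0) {
    r <- min(left, max(1L, as.integer(round(stats::rexp(1, 1 / mean_run)))))
    runs <- c(runs, r)
    left <- left - r
  }
  k <- length(runs)
  n_off <- n - n_on
  if (k > n_off + 1L) {
    # too many runs to keep them separated: merge into fewer runs
    runs <- diff(round(seq(0, n_on, length.out = max(1L, n_off + 1L) + 1L)))
    runs <- runs[runs > 0]
    k <- length(runs)
  }
  # distribute the off frames into k + 1 gaps (first and last may be empty)
  cuts <- sort(sample.int(n_off + k, k))
  gaps <- diff(c(0, cuts, n_off + k)) - c(rep(1L, k), 0L)
  pos <- 1L
  for (i in seq_len(k)) {
    pos <- pos + gaps[i]
    state[pos:(pos + runs[i] - 1L)] <- TRUE
    pos <- pos + runs[i]
  }
  state
}

#' Simulate per-frame eye and mouth state streams with exact fractions
#'
#' Exactly `round(closed_fraction * n_frames)` frames are labelled closed,
#' placed in blink-length runs, and likewise for yawn frames; the realized
#' fractions recorded as ground truth equal the label counts divided by the
#' frame count exactly. Openness scores are 1 for open/normal frames and 0
#' for closed/yawn frames (for the mouth the score is *openness*, so yawns
#' score 1 and normal frames 0), plus optional Gaussian noise.
#'
#' @param cfg an [eye_state_sim_config()].
#' @return list with `frames` (data.frame: frame, time_s, eye_state,
#'   mouth_state, eye_openness, mouth_openness) and `truth` (true_perclos,
#'   true_yawn_rate, n_frames).
#' @export
simulate_eye_state_stream <- function(cfg) {
  stopifnot(inherits(cfg, "eye_state_sim_config"))
  n <- as.integer(round(cfg$fps * cfg$window_s))
  n_closed <- as.integer(round(cfg$closed_fraction * n))
  n_yawn <- as.integer(round(cfg$yawn_fraction * n))
  with_seed(cfg$seed, {
    closed <- place_runs(n, n_closed, cfg$blink_mean_dur_s * cfg$fps)
    yawn <- place_runs(n, n_yawn, cfg$yawn_mean_dur_s * cfg$fps)
    eye_open <- as.numeric(!closed)
    mouth_open <- as.numeric(yawn)
    if (cfg$score_noise_sd > 0) {
      eye_open <- eye_open + stats::rnorm(n, 0, cfg$score_noise_sd)
      mouth_open <- mouth_open + stats::rnorm(n, 0, cfg$score_noise_sd)
    }
    frames <- data.frame(
      frame = seq_len(n) - 1L,
      time_s = (seq_len(n) - 1L) / cfg$fps,
      eye_state = ifelse(closed, "closed", "open"),
      mouth_state = ifelse(yawn, "yawn", "normal"),
      eye_openness = eye_open,
      mouth_openness = mouth_open,
      stringsAsFactors = FALSE
    )
    list(frames = frames,
         truth = list(true_perclos = n_closed / n,
                      true_yawn_rate = n_yawn / n,
                      n_frames = n, seed = cfg$seed))
  })
}

#' Simulate per-frame ROI pixel arrays reproducing a given trace
#'
#' For each frame, the pixels inside the mask are filled with the trace value
#' plus an exactly zero-mean perturbation, so the masked spatial average
#' reproduces the input trace to floating tolerance. Pixels outside the mask
#' are filled with independent clutter.
#'
#' @param trace numeric intensity series, one value per frame.
#' @param mask logical matrix; `TRUE` marks ROI pixels (at least one).
#' @param perturb_sd standard deviation of the in-mask perturbation.
#' @param seed integer seed.
#' @return list of numeric matrices, one per frame, with `dim(mask)`.
#' @export
simulate_roi_frames <- function(trace, mask, perturb_sd = 0, seed = 1L) {
  if (!is.matrix(mask) || !is.logical(mask)) stopf("mask must be a logical matrix")
  m <- sum(mask)
  if (m == 0L) stopf("mask is empty: at least one ROI pixel is required")
  if (!all(is.finite(trace))) stopf("trace must be finite")
  with_seed(seed, lapply(trace, function(v) {
    fr <- matrix(stats::rnorm(length(mask), mean = v, sd = max(perturb_sd, 1)),
                 nrow = nrow(mask))
    if (perturb_sd > 0 && m > 1L) {
      p <- stats::rnorm(m, 0, perturb_sd)
      fr[mask] <- v + (p - mean(p))
    } else {
      fr[mask] <- v
    }
    fr
  }))
}

#' Regime presets for awake and fatigued drivers
#'
#' Returns the generator configurations that define the two synthetic
#' regimes. Relative to the awake state, the fatigue regime has a lower mean
#' heart rate, a larger LF and smaller HF interval modulation (higher LF/HF),
#' more interval jitter (higher SD), and higher eye-closure and yawn
#' fractions. The direction of every change follows the physiology of
#' drowsiness; the magnitudes are free generator parameters, fixed here once.
#'
#' @param preset `"awake"` or `"fatigue"`.
#' @param duration_s RR simulation duration per window, seconds.
#' @param seed integer seed.
#' @return list with elements `rr` ([rr_sim_config()]) and
#'   `eye` ([eye_state_sim_config()]), plus `label` (0 awake / 1 fatigue).
#' @export
regime_params <- function(preset = c("awake", "fatigue"), duration_s = 120,
                          seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "awake") {
    list(rr = rr_sim_config(duration_s = duration_s, mean_hr_bpm = 72,
                            lf_amp_s = 0.020, hf_amp_s = 0.028,
                            jitter_sd_s = 0.008, seed = seed),
         eye = eye_state_sim_config(closed_fraction = 0.08,
                                    yawn_fraction = 0.01,
                                    seed = derive_seed(seed, "eye")),
         label = 0L)
  } else {
    list(rr = rr_sim_config(duration_s = duration_s, mean_hr_bpm = 62,
                            lf_amp_s = 0.055, hf_amp_s = 0.025,
                            jitter_sd_s = 0.022, seed = seed),
         eye = eye_state_sim_config(closed_fraction = 0.35,
                                    yawn_fraction = 0.12,
                                    seed = derive_seed(seed, "eye")),
         label = 1L)
  }
}

#' Simulate a full labelled driving session
#'
#' Generates one synthetic session made of consecutive 60 s fusion windows,
#' each in an awake or fatigued regime: a continuous pulse trace (rendered
#' from the per-window RR series), per-frame eye/mouth streams, and a
#' ground-truth record with per-window labels.
#'
#' @param states character vector of per-window regimes (`"awake"` /
#'   `"fatigue"`); or use `preset` for a constant-state session.
#' @param preset regime used for every window when `states` is `NULL`.
#' @param n_windows number of 60 s windows when `preset` is used.
#' @param seed root seed; per-stream seeds are derived from it.
#' @param fs_hz trace sampling rate (frames/s).
#' @param fps facial stream frame rate.
#' @param noise_sd,drift_amp trace noise and drift amplitude passed to
#'   [render_pulse_waveform()].
#' @return a list of class `sim_session`: `trace` (data.frame time_s, value),
#'   `fs_hz`, `frames` (facial stream), `fps`, `beat_times`, `truth`
#'   (per-window labels and regime parameters), `seed`.
#' @export
simulate_session <- function(states = NULL, preset = "awake", n_windows = 5,
                             seed = 1L, fs_hz = 30, fps = 20,
                             noise_sd = 0.05, drift_amp = 0.3) {
  if (is.null(states)) states <- rep(preset, n_windows)
  if (!all(states %in% c("awake", "fatigue"))) stopf("unknown regime in 'states'")
  window_s <- 60
  intervals <- numeric(0)
  frames <- NULL
  labels <- integer(length(states))
  t_off <- 0
  for (w in seq_along(states)) {
    rp <- regime_params(states[w], duration_s = window_s,
                        seed = derive_seed(seed, paste0("win", w)))
    rr <- simulate_rr_series(rp$rr)
    intervals <- c(intervals, rr$intervals)
    es <- simulate_eye_state_stream(rp$eye)
    es$frames$time_s <- es$frames$time_s + t_off
    es$frames$frame <- es$frames$frame + as.integer(round(t_off * fps))
    es$frames$window <- w
    frames <- rbind(frames, es$frames)
    labels[w] <- rp$label
    t_off <- t_off + window_s
  }
  beat_times <- c(0, cumsum(intervals))
  pcfg <- pulse_sim_config(fs_hz = fs_hz, noise_sd = noise_sd,
                           drift_amp = drift_amp,
                           seed = derive_seed(seed, "pulse"))
  duration <- window_s * length(states)
  x <- render_pulse_waveform(beat_times, pcfg, duration_s = duration)
  trace <- data.frame(time_s = (seq_along(x) - 1) / fs_hz, value = x)
  structure(list(trace = trace, fs_hz = fs_hz, frames = frames, fps = fps,
                 beat_times = beat_times, intervals = intervals,
                 truth = list(labels = labels, states = states,
                              window_s = window_s),
                 seed = as.integer(seed)),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("Synthetic driving session: %d windows of %d s (%d fatigued)\n",
              length(x$truth$labels), x$truth$window_s, sum(x$truth$labels)))
  cat(sprintf("  trace: %d samples at %g Hz; facial stream: %d frames at %g fps\n",
              nrow(x$trace), x$fs_hz, nrow(x$frames), x$fps))
  invisible(x)
}

#' Write a simulated session to a directory as CSV + JSON
#'
#' Writes `trace.csv` (time_s, value), `face.csv` (per-frame states and
#' openness scores) and a `truth.json` ground-truth sidecar.
#'
#' @param session a [simulate_session()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "sim_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$trace, file.path(dir, "trace.csv"), row.names = FALSE)
  utils::write.csv(session$frames, file.path(dir, "face.csv"), row.names = FALSE)
  truth <- session$truth
  truth$beat_times <- session$beat_times
  truth$fs_hz <- session$fs_hz
  truth$fps <- session$fps
  truth$seed <- session$seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir directory containing `trace.csv` and `face.csv` (and
#'   optionally `truth.json`).
#' @return a list of class `sim_session` (truth is `NULL` when absent).
#' @export
read_session <- function(dir) {
  tr_path <- file.path(dir, "trace.csv")
  fc_path <- file.path(dir, "face.csv")
  if (!file.exists(tr_path) || !file.exists(fc_path))
    stopf("session directory '%s' must contain trace.csv and face.csv", dir)
  trace <- utils::read.csv(tr_path)
  frames <- utils::read.csv(fc_path)
  truth <- NULL
  fs_hz <- 1 / stats::median(diff(trace$time_s))
  fps <- 1 / stats::median(diff(frames$time_s[frames$time_s < 10]))
  beat_times <- NULL
  if (file.exists(file.path(dir, "truth.json"))) {
    truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
    fs_hz <- truth$fs_hz %||% fs_hz
    fps <- truth$fps %||% fps
    beat_times <- truth$beat_times
  }
  structure(list(trace = trace, fs_hz = fs_hz, frames = frames, fps = fps,
                 beat_times = beat_times, truth = truth),
            class = "sim_session")
}
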