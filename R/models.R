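# Synthetic training-set builders and the joint model-training wrapper.
# Every sample is generated from the awake/fatigue regime presets in
# regime_params(); labels are the regime labels.

#' Build a labelled heart-rate feature dataset from the regime generator
#'
#' Each sample is the length-1024 heart-rate input vector for one simulated
#' window in a given regime. With `pathway = "signal"` (the default) the
#' window is pushed through the full extraction chain — pulse rendering
#' with session-typical noise and drift, SSA denoising and beat detection —
#' so the training distribution matches what [run_pipeline()] extracts;
#' `pathway = "rr"` computes the features directly from the true RR series.
#'
#' @param n_per_class samples per regime.
#' @param seed integer root seed.
#' @param duration_s RR duration per sample, seconds.
#' @param pathway `"signal"` (full extraction chain) or `"rr"` (true
#'   intervals).
#' @param noise_sd,drift_amp trace noise and drift used by the signal
#'   pathway (matching [simulate_session()] defaults).
#' @return list with matrix `x` (rows = samples) and integer labels `y`.
#' @export
make_hr_dataset <- function(n_per_class, seed = 1L, duration_s = 62,
                            pathway = c("signal", "rr"),
                            noise_sd = 0.05, drift_amp = 0.3) {
  pathway <- match.arg(pathway)
  xs <- list(); ys <- integer(0)
  for (cls in c("awake", "fatigue")) {
    for (i in seq_len(n_per_class)) {
      rp <- regime_params(cls, duration_s = duration_s,
                          seed = derive_seed(seed, paste0("hr-", cls, "-", i)))
      rr <- simulate_rr_series(rp$rr)
      bt <- if (pathway == "rr") rr$beat_times else {
        x <- render_pulse_waveform(rr$beat_times, pulse_sim_config(
          fs_hz = 30, pulse_width_s = 0.5, noise_sd = noise_sd,
          drift_amp = drift_amp,
          seed = derive_seed(seed, paste0("hrn-", cls, "-", i))))
        detect_beats(ssa_denoise(x, 30)$filtered, 30)$peak_times
      }
      xs[[length(xs) + 1L]] <- build_hr_input(hr_feature_track(bt))
      ys <- c(ys, rp$label)
    }
  }
  list(x = do.call(rbind, xs), y = ys)
}

#' Build a labelled facial feature dataset from the regime generator
#'
#' Each sample is the length-600 face input vector computed from one
#' simulated 60 s eye/mouth stream; openness scores carry Gaussian noise of
#' SD `score_noise_sd` so the two regimes overlap realistically.
#'
#' @param n_per_class samples per regime.
#' @param seed integer root seed.
#' @param score_noise_sd openness score noise (default 0.15).
#' @return list with matrix `x` and integer labels `y`.
#' @export
make_face_dataset <- function(n_per_class, seed = 1L, score_noise_sd = 0.15) {
  xs <- list(); ys <- integer(0)
  for (cls in c("awake", "fatigue")) {
    for (i in seq_len(n_per_class)) {
      rp <- regime_params(cls, seed = derive_seed(seed, paste0("face-", cls, "-", i)))
      cfg <- rp$eye
      cfg$score_noise_sd <- score_noise_sd
      st <- simulate_eye_state_stream(cfg)
      xs[[length(xs) + 1L]] <- build_face_input(st$frames$eye_openness,
                                                st$frames$mouth_openness)
      ys <- c(ys, rp$label)
    }
  }
  list(x = do.call(rbind, xs), y = ys)
}

# Markov regime sequence with persistence.
simulate_state_sequence <- function(n_windows, p_switch = 0.2, seed = 1L) {
  with_seed(seed, {
    s <- character(n_windows)
    s[1] <- sample(c("awake", "fatigue"), 1)
    for (i in seq_len(n_windows - 1L))
      s[i + 1L] <- if (stats::runif(1) < p_switch)
        setdiff(c("awake", "fatigue"), s[i]) else s[i]
    s
  })
}

#' Build per-session fusion sequences from trained single-modality models
#'
#' Simulates sessions whose per-window regimes follow a persistent Markov
#' chain, computes the heart-rate and face model inputs per window, runs
#' both fitted CNNs, and returns the per-window concatenated class
#' probabilities as BiLSTM input sequences with the regime labels.
#'
#' @param hr_model,face_model fitted [fit_cnn()] models.
#' @param n_sessions number of sessions.
#' @param n_windows 60 s windows per session.
#' @param p_switch per-window regime switch probability.
#' @param score_noise_sd facial score noise.
#' @param seed integer root seed.
#' @return list with `sequences` (list of T x 4 matrices) and `labels`
#'   (list of 0/1 vectors).
#' @export
make_fusion_dataset <- function(hr_model, face_model, n_sessions,
                                n_windows = 8L, p_switch = 0.2,
                                score_noise_sd = 0.15, seed = 1L) {
  sequences <- vector("list", n_sessions)
  labels <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    states <- simulate_state_sequence(n_windows, p_switch,
                                      derive_seed(seed, paste0("states-", s)))
    X <- matrix(0, n_windows, 4L)
    y <- integer(n_windows)
    for (w in seq_len(n_windows)) {
      rp <- regime_params(states[w], duration_s = 62,
                          seed = derive_seed(seed, paste0("fus-", s, "-", w)))
      rr <- simulate_rr_series(rp$rr)
      px <- render_pulse_waveform(rr$beat_times, pulse_sim_config(
        fs_hz = 30, pulse_width_s = 0.5, noise_sd = 0.05, drift_amp = 0.3,
        seed = derive_seed(seed, paste0("fusn-", s, "-", w))))
      bt <- detect_beats(ssa_denoise(px, 30)$filtered, 30)$peak_times
      hr_x <- build_hr_input(hr_feature_track(bt))
      ecfg <- rp$eye
      ecfg$score_noise_sd <- score_noise_sd
      st <- simulate_eye_state_stream(ecfg)
      face_x <- build_face_input(st$frames$eye_openness,
                                 st$frames$mouth_openness)
      X[w, ] <- c(predict(hr_model, hr_x), predict(face_model, face_x))
      y[w] <- rp$label
    }
    sequences[[s]] <- X
    labels[[s]] <- y
  }
  list(sequences = sequences, labels = labels)
}

#' Train the full fatigue model stack on synthetic regimes
#'
#' Fits the heart-rate CNN, the face CNN and the BiLSTM fusion head on
#' freshly generated synthetic datasets, deterministically for a fixed seed.
#'
#' @param seed integer root seed.
#' @param n_per_class CNN training samples per regime.
#' @param n_sessions fusion training sessions.
#' @param epochs_cnn,epochs_bilstm training epochs.
#' @param verbose print training progress.
#' @return list of class `fatigue_models` with elements `hr`, `face`,
#'   `fusion`.
#' @export
train_fatigue_models <- function(seed = 1L, n_per_class = 60L,
                                 n_sessions = 30L, epochs_cnn = 20L,
                                 epochs_bilstm = 30L, verbose = FALSE) {
  hr_d <- make_hr_dataset(n_per_class, seed = derive_seed(seed, "hr-data"))
  hr <- fit_cnn(hr_d$x, hr_d$y, hr_cnn_config(), epochs = epochs_cnn,
                seed = derive_seed(seed, "hr-fit"), verbose = verbose)
  face_d <- make_face_dataset(n_per_class, seed = derive_seed(seed, "face-data"))
  face <- fit_cnn(face_d$x, face_d$y, face_cnn_config(), epochs = epochs_cnn,
                  seed = derive_seed(seed, "face-fit"), verbose = verbose)
  fus_d <- make_fusion_dataset(hr, face, n_sessions,
                               seed = derive_seed(seed, "fusion-data"))
  fusion <- fit_bilstm(fus_d$sequences, fus_d$labels, epochs = epochs_bilstm,
                       seed = derive_seed(seed, "fusion-fit"), verbose = verbose)
  structure(list(hr = hr, face = face, fusion = fusion,
                 seed = as.integer(seed)),
            class = "fatigue_models")
}

#' @export
print.fatigue_models <- function(x, ...) {
  cat("Fatigue model stack:\n")
  print(x$hr); print(x$face); print(x$fusion)
  invisible(x)
}

#' Serialize a fitted model stack to a portable text checkpoint
#'
#' Writes a JSON file containing the architecture headers and all weights,
#' readable back with [load_fatigue_models()].
#'
#' @param models a [train_fatigue_models()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_fatigue_models <- function(models, path) {
  stopifnot(inherits(models, "fatigue_models"))
  enc <- function(x) {
    if (is.matrix(x)) list(`_dim` = dim(x), `_data` = as.vector(x))
    else if (is.list(x)) lapply(x, enc)
    else x
  }
  jsonlite::write_json(enc(unclass(lapply(models, unclass))), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model stack written by [save_fatigue_models()]
#'
#' @param path checkpoint file path.
#' @return a `fatigue_models` list.
#' @export
load_fatigue_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  dec <- function(x) {
    if (is.list(x) && !is.null(x[["_dim"]]))
      matrix(as.numeric(x[["_data"]]), as.integer(x[["_dim"]])[1])
    else if (is.list(x)) lapply(x, dec)
    else x
  }
  raw <- dec(raw)
  fix_cnn <- function(m) {
    m$cfg <- structure(m$cfg, class = "cnn_config")
    structure(m, class = "fatigue_cnn")
  }
  structure(list(hr = fix_cnn(raw$hr), face = fix_cnn(raw$face),
                 fusion = structure(raw$fusion, class = "fatigue_bilstm"),
                 seed = raw$seed),
            class = "fatigue_models")
}
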