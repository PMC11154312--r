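#' Construct a five-point landmark set
#'
#' Coordinates are 0-based pixels with the origin at the top-left of the
#' image, x growing rightwards and y downwards.
#'
#' @param left_eye,right_eye,nose,mouth_left,mouth_right numeric `(x, y)`
#'   pairs. "Left" refers to the image frame, so `left_eye` must lie left of
#'   `right_eye` (smaller x).
#' @return a list of class `landmark_set`.
#' @export
landmark_set <- function(left_eye, right_eye, nose, mouth_left, mouth_right) {
  pts <- list(left_eye = left_eye, right_eye = right_eye, nose = nose,
              mouth_left = mouth_left, mouth_right = mouth_right)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p)))
      stopf("landmark '%s' must be a finite (x, y) pair", nm)
  }
  if (left_eye[1] >= right_eye[1])
    stopf("left_eye.x (%g) must be less than right_eye.x (%g)",
          left_eye[1], right_eye[1])
  structure(pts, class = "landmark_set")
}

region_box <- function(center, w, h, alpha) {
  if (w <= 0 || h <= 0) stopf("box width and height must be positive")
  structure(list(center = center, w = w, h = h, alpha = alpha),
            class = "region_box")
}

#' @export
print.region_box <- function(x, ...) {
  cat(sprintf("Region box: center (%.2f, %.2f), %.2f x %.2f px, rotation %.1f deg\n",
              x$center[1], x$center[2], x$w, x$h, x$alpha * 180 / pi))
  invisible(x)
}

#' Eye region boxes from landmark geometry
#'
#' The line joining the two eye centres defines the box rotation `alpha`
#' (its angle against the horizontal). Each eye gets a box of width
#' `scale * interocular distance` and height `w / 2`, centred on that eye
#' and rotated by `alpha`.
#'
#' @param lm a [landmark_set()].
#' @param scale eye-box width as a fraction of the interocular distance
#'   (default 0.6).
#' @return list with `left` and `right` region boxes.
#' @export
eye_boxes <- function(lm, scale = 0.6) {
  stopifnot(inherits(lm, "landmark_set"))
  d <- lm$right_eye - lm$left_eye
  dist <- sqrt(sum(d^2))
  if (dist == 0) stopf("eye landmarks coincide")
  alpha <- atan2(d[2], d[1])
  w <- scale * dist
  list(left = region_box(lm$left_eye, w, w / 2, alpha),
       right = region_box(lm$right_eye, w, w / 2, alpha))
}

#' Mouth region box from landmark geometry
#'
#' The lip corners define the baseline; `d` is the perpendicular distance
#' from the nose landmark to that line. The box follows the baseline
#' rotation, spans the lip-corner distance in width, and extends from `d/2`
#' on the nose side of the baseline to `5d/3` on the far side (total height
#' `13d/6`).
#'
#' @param lm a [landmark_set()].
#' @return a region box.
#' @export
mouth_box <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  b <- lm$mouth_right - lm$mouth_left
  blen <- sqrt(sum(b^2))
  if (blen == 0) stopf("mouth corner landmarks coincide")
  u <- b / blen
  # unit normal of the lip line, oriented towards the nose
  nrm <- c(-u[2], u[1])
  rel <- lm$nose - lm$mouth_left
  d_signed <- sum(rel * nrm)
  if (d_signed == 0) stopf("nose lies on the lip-corner line: degenerate geometry")
  if (d_signed < 0) { nrm <- -nrm; d_signed <- -d_signed }
  d <- d_signed
  mid <- (lm$mouth_left + lm$mouth_right) / 2
  # edges at +d/2 (nose side) and -5d/3 along the nose-pointing normal
  center <- mid + nrm * (d / 2 - 13 * d / 6 / 2)
  region_box(center, blen, 13 * d / 6, atan2(u[2], u[1]))
}

#' Classify per-frame eye and mouth states from openness scores
#'
#' Default threshold rule: a frame's eyes are closed when the eye openness
#' falls below `eye_threshold`; frames belong to a yawn when the mouth
#' openness exceeds `mouth_threshold` for at least `min_yawn_run` consecutive
#' frames. A fitted classifier (e.g. the face 1-D CNN) can be plugged in via
#' `classifier`, which receives the score data.frame and must return a
#' data.frame with `eye_state` and `mouth_state` columns.
#'
#' @param scores data.frame with columns `frame`, `eye_openness`,
#'   `mouth_openness` (one row per frame, frames consecutive).
#' @param eye_threshold,mouth_threshold decision thresholds on the scores.
#' @param min_yawn_run minimum yawn run length in frames (default 1).
#' @param classifier optional function overriding the threshold rule.
#' @return data.frame with `frame`, `eye_state` ("open"/"closed") and
#'   `mouth_state` ("normal"/"yawn").
#' @export
classify_states <- function(scores, eye_threshold = 0.5, mouth_threshold = 0.5,
                            min_yawn_run = 1L, classifier = NULL) {
  need <- c("frame", "eye_openness", "mouth_openness")
  if (!all(need %in% names(scores)))
    stopf("scores must have columns %s", paste(need, collapse = ", "))
  fr <- scores$frame
  gaps <- which(diff(fr) != 1L)
  if (length(gaps))
    stopf("missing frames after: %s",
          paste(utils::head(fr[gaps], 5), collapse = ", "))
  if (!is.null(classifier)) {
    out <- classifier(scores)
    return(data.frame(frame = fr, eye_state = out$eye_state,
                      mouth_state = out$mouth_state, stringsAsFactors = FALSE))
  }
  closed <- scores$eye_openness < eye_threshold
  yawn_raw <- scores$mouth_openness > mouth_threshold
  if (min_yawn_run > 1L && any(yawn_raw)) {
    r <- rle(yawn_raw)
    r$values <- r$values & r$lengths >= min_yawn_run
    yawn_raw <- inverse.rle(r)
  }
  data.frame(frame = fr,
             eye_state = ifelse(closed, "closed", "open"),
             mouth_state = ifelse(yawn_raw, "yawn", "normal"),
             stringsAsFactors = FALSE)
}

#' PERCLOS and yawn rate over one detection window
#'
#' Exact count ratios over a fully populated window: PERCLOS P is the number
#' of closed-eye frames divided by the window frame count, and the yawn rate
#' is the yawn-frame fraction.
#'
#' @param states data.frame from [classify_states()].
#' @param window_frames frames per window (default 1200: 60 s at 20 fps).
#' @return list of class `face_window_rates`: `perclos`, `yawn_rate`,
#'   `window_frames`, and the raw `closed_frames` / `yawn_frames` counts.
#' @export
window_rates <- function(states, window_frames = 1200L) {
  if (nrow(states) != window_frames)
    stopf("window underfull: %d frames present, %d required",
          nrow(states), window_frames)
  closed <- sum(states$eye_state == "closed")
  yawn <- sum(states$mouth_state == "yawn")
  structure(list(perclos = closed / window_frames,
                 yawn_rate = yawn / window_frames,
                 window_frames = as.integer(window_frames),
                 closed_frames = closed, yawn_frames = yawn),
            class = "face_window_rates")
}

#' @export
print.face_window_rates <- function(x, ...) {
  cat(sprintf("PERCLOS %.3f (%d/%d frames), yawn rate %.3f (%d/%d)\n",
              x$perclos, x$closed_frames, x$window_frames,
              x$yawn_rate, x$yawn_frames, x$window_frames))
  invisible(x)
}

#' Read a five-point landmark stream from CSV
#'
#' Expected columns: `frame, lx, ly, rx, ry, nx, ny, mlx, mly, mrx, mry`
#' (eye, eye, nose, mouth-corner, mouth-corner coordinates per frame).
#'
#' @param path CSV file path.
#' @return list of [landmark_set()] objects, one per frame.
#' @export
read_landmarks <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame", "lx", "ly", "rx", "ry", "nx", "ny", "mlx", "mly", "mrx", "mry")
  if (!all(need %in% names(d)))
    stopf("landmark CSV must have columns %s", paste(need, collapse = ", "))
  lapply(seq_len(nrow(d)), function(i)
    landmark_set(c(d$lx[i], d$ly[i]), c(d$rx[i], d$ry[i]), c(d$nx[i], d$ny[i]),
                 c(d$mlx[i], d$mly[i]), c(d$mrx[i], d$mry[i])))
}
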