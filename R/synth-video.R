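#' Generate synthetic actor track points
#'
#' Emulates the per-frame face and hand landmark tables produced by video
#' tracking of an actor: anatomically ordered landmarks (eyebrows above
#' pupils above nose tip above mouth) laid out on an elliptical face around
#' the screen center, translated by smooth low-frequency sinusoidal motion;
#' the two hands move independently below the face.  Left/right are in
#' actor reference, so the actor's left hand sits at larger screen x.
#' Deterministic for a fixed seed.
#'
#' @param n_frames number of video frames.
#' @param fps frame rate (default 25).
#' @param seed RNG seed for motion phases.
#' @param motion_px amplitude of the face motion in pixels (0 freezes all
#'   landmarks).
#' @param center screen position `c(x, y)` of the face center, pixels.
#' @param scale overall size factor of the face layout.
#' @return long data frame `frame`, `t_ms`, `landmark`, `x`, `y`.
#' @export
gen_actor_trackpoints <- function(n_frames, fps = 25, seed = 1,
                                  motion_px = 15, center = c(960, 420),
                                  scale = 1) {
  stopifnot(n_frames >= 1)
  # actor-left = screen +x; offsets (x, y) from face center, pixels
  layout <- rbind(
    eyebrow_outer_left = c(95, -95), eyebrow_inner_left = c(25, -105),
    eyebrow_middle_left = c(60, -115),
    eyebrow_outer_right = c(-95, -95), eyebrow_inner_right = c(-25, -105),
    eyebrow_middle_right = c(-60, -115),
    pupil_left = c(48, -60), pupil_right = c(-48, -60),
    nose_tip = c(0, 20), nostril_left = c(26, 28), nostril_right = c(-26, 28),
    mouth_top = c(0, 62), mouth_bottom = c(0, 108),
    mouth_left = c(52, 85), mouth_right = c(-52, 85),
    hand_left = c(260, 380), hand_right = c(-260, 400)) * scale
  ph <- fr <- NULL
  withr::with_seed(seed, {
    ph <- stats::runif(6, 0, 2 * pi)
    fr <- stats::runif(6, 0.4, 1.5)     # Hz, slow natural movement
  })
  t_s <- (seq_len(n_frames) - 1) / fps
  out <- do.call(rbind, lapply(seq_len(n_frames), function(i) {
    face_dx <- motion_px * sin(2 * pi * fr[1] * t_s[i] + ph[1])
    face_dy <- motion_px * 0.6 * sin(2 * pi * fr[2] * t_s[i] + ph[2])
    hand_l <- c(3, 2) * motion_px * c(sin(2 * pi * fr[3] * t_s[i] + ph[3]),
                                      sin(2 * pi * fr[4] * t_s[i] + ph[4]))
    hand_r <- c(3, 2) * motion_px * c(sin(2 * pi * fr[5] * t_s[i] + ph[5]),
                                      sin(2 * pi * fr[6] * t_s[i] + ph[6]))
    x <- center[1] + layout[, 1] + face_dx
    y <- center[2] + layout[, 2] + face_dy
    x[rownames(layout) == "hand_left"] <-
      x[rownames(layout) == "hand_left"] + hand_l[1] - face_dx
    y[rownames(layout) == "hand_left"] <-
      y[rownames(layout) == "hand_left"] + hand_l[2] - face_dy
    x[rownames(layout) == "hand_right"] <-
      x[rownames(layout) == "hand_right"] + hand_r[1] - face_dx
    y[rownames(layout) == "hand_right"] <-
      y[rownames(layout) == "hand_right"] + hand_r[2] - face_dy
    data.frame(frame = i, t_ms = (i - 1) / fps * 1000,
               landmark = rownames(layout), x = x, y = y)
  }))
  rownames(out) <- NULL
  out
}
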