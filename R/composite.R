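#' Composite the scotoma over a frame at the point of gaze
#'
#' Alpha-blends the blurred frame over the original with the scotoma mask
#' anchored on gaze: `out = (1 - alpha) * frame + alpha * blurred`, with the
#' mask's anchor pixel placed at the (rounded) gaze position.  Pixels
#' outside the mask footprint are untouched, and parts of the mask falling
#' off-screen are cropped, so a gaze far outside the frame leaves it
#' unchanged.
#'
#' @param frame,blurred numeric matrices of the same size (rows = y).
#' @param m a [build_scotoma_mask()] object.
#' @param gaze numeric `c(x, y)` gaze position in pixels; may be off-screen.
#' @return composited frame.
#' @export
composite_scotoma <- function(frame, blurred, m, gaze) {
  stopifnot(inherits(m, "scotoma_mask"))
  if (!all(dim(frame) == dim(blurred)))
    stop("frame and blurred frame differ in size")
  a <- m$alpha
  gx <- round(gaze[1]); gy <- round(gaze[2])
  # top-left of the mask in frame coordinates
  x0 <- gx - round(m$anchor["x"]) + 1
  y0 <- gy - round(m$anchor["y"]) + 1
  fx <- max(1, x0):min(ncol(frame), x0 + ncol(a) - 1)
  fy <- max(1, y0):min(nrow(frame), y0 + nrow(a) - 1)
  if (length(fx) == 0 || length(fy) == 0 || fx[1] > fx[length(fx)] ||
      fy[1] > fy[length(fy)])
    return(frame)
  ax <- fx - x0 + 1
  ay <- fy - y0 + 1
  sub_a <- a[ay, ax, drop = FALSE]
  out <- frame
  out[fy, fx] <- (1 - sub_a) * frame[fy, fx] + sub_a * blurred[fy, fx]
  out
}

#' Render a gaze-contingent degraded clip
#'
#' Applies the scotoma degradation to every frame of a clip: each frame is
#' Gaussian low-pass filtered ([gaussian_lowpass_frame()]) and composited
#' with the mask centered on the gaze sample nearest the frame's timestamp.
#' The mask orientation is fixed within a trial (pass a mask already set to
#' the trial's orientation, randomized across trials by the caller).
#'
#' @param frames list of numeric matrices (the clip).
#' @param frame_times numeric vector of frame timestamps, ms.
#' @param gaze_trace data frame with columns `t_ms`, `x_px`, `y_px`.
#' @param m a [build_scotoma_mask()] object.
#' @param g a [screen_geometry()].
#' @param cutoff blur FWHM cutoff, cycles/degree.
#' @return list of degraded frames; attribute `"gaze_index"` records which
#'   gaze sample was used for each frame.
#' @export
render_degraded_clip <- function(frames, frame_times, gaze_trace,
                                 m, g = screen_geometry(), cutoff = 0.15) {
  if (is.null(gaze_trace) || nrow(gaze_trace) == 0)
    stop("empty gaze trace")
  if (length(frames) != length(frame_times))
    stop("frames and frame_times differ in length")
  idx <- vapply(frame_times, function(t)
    which.min(abs(gaze_trace$t_ms - t)), integer(1))
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    bl <- gaussian_lowpass_frame(frames[[i]], cutoff, g)
    out[[i]] <- composite_scotoma(
      frames[[i]], bl, m,
      c(gaze_trace$x_px[idx[i]], gaze_trace$y_px[idx[i]]))
  }
  attr(out, "gaze_index") <- idx
  out
}
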