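#' Screen geometry in pixels and degrees of visual angle
#'
#' Defaults describe the study display: 1920 x 1080 pixels subtending
#' 43 x 24.8 degrees of visual angle at the viewing distance.
#'
#' @param width_px,height_px display size in pixels.
#' @param width_deg,height_deg display size in degrees of visual angle.
#' @return a `screen_geometry` object.
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            width_deg = 43, height_deg = 24.8) {
  vals <- c(width_px, height_px, width_deg, height_deg)
  if (any(!is.finite(vals) | vals <= 0))
    stop("all geometry fields must be positive and finite")
  structure(list(width_px = width_px, height_px = height_px,
                 width_deg = width_deg, height_deg = height_deg),
            class = "screen_geometry")
}

#' Pixels per degree of visual angle
#'
#' @param g a [screen_geometry()].
#' @param axis `"horizontal"` (default) or `"vertical"`.
#' @return pixels per degree along the requested axis.
#' @examples
#' pixels_per_degree(screen_geometry()) # 44.65
#' @export
pixels_per_degree <- function(g, axis = c("horizontal", "vertical")) {
  stopifnot(inherits(g, "screen_geometry"))
  axis <- match.arg(axis)
  if (axis == "horizontal") g$width_px / g$width_deg
  else g$height_px / g$height_deg
}

#' Display diagonal in degrees of visual angle
#'
#' The saccade-amplitude filter uses the display diagonal as the upper
#' bound on plausible amplitudes (49.6 degrees for the default geometry).
#'
#' @param g a [screen_geometry()].
#' @return diagonal extent in degrees.
#' @export
display_diagonal_deg <- function(g = screen_geometry()) {
  sqrt(g$width_deg^2 + g$height_deg^2)
}
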