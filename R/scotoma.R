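#' Build the relative central scotoma mask
#'
#' Generates the soft-edged alpha mask used to render a gaze-contingent
#' relative central scotoma: a semi-circular but irregular shape sized
#' 731 x 497 pixels (roughly 17 x 11.5 degrees on the default display).
#' The base shape is a half-ellipse with a flattened vertical edge on the
#' left, its boundary perturbed by low-frequency sinusoids drawn from the
#' seed, so the mask is irregular yet exactly reproducible.  Alpha is 1 in
#' the core and decays to 0 over a raised-cosine ring at the boundary
#' (soft edges).  The mask can be delivered in any of four orientations
#' (axis flips), which are randomized across trials in the experiment.
#'
#' @param seed RNG seed fixing the irregular boundary.
#' @param orientation one of `"original"`, `"h-flip"`, `"v-flip"`,
#'   `"hv-flip"`.
#' @param width,height bounding-box size of the mask in pixels.
#' @param edge_px width of the raised-cosine soft edge, pixels.
#' @return a `scotoma_mask` object: `alpha` (height x width matrix in
#'   \[0, 1\], rows = y), `orientation`, and `anchor`, the (x, y) mask pixel
#'   that sits on the point of gaze (the bounding-box center).
#' @export
build_scotoma_mask <- function(seed = 1,
                               orientation = c("original", "h-flip",
                                               "v-flip", "hv-flip"),
                               width = 731, height = 497, edge_px = 40) {
  orientation <- match.arg(orientation)
  # irregular boundary: radial perturbation by low-order harmonics
  k <- 2:6
  amp <- phase <- NULL
  withr::with_seed(seed, {
    amp <- stats::runif(length(k), 0.02, 0.10) / sqrt(k)
    phase <- stats::runif(length(k), 0, 2 * pi)
  })
  inside <- function(xn, yn) {
    # xn, yn: normalized coordinates (vectors), shape centered at 0
    th <- atan2(yn, xn)
    r <- sqrt(xn^2 + yn^2)
    pert <- rep(0, length(th))
    for (i in seq_along(k)) pert <- pert + amp[i] * sin(k[i] * th + phase[i])
    flat <- xn >= -0.72                 # flattened vertical edge on the left
    (r <= 1 + pert) & flat
  }
  # pass 1: locate the bounding box of the shape in normalized space
  u <- seq(-1.3, 1.3, length.out = 600)
  g <- expand.grid(x = u, y = u)
  hit <- inside(g$x, g$y)
  xr <- range(g$x[hit]); yr <- range(g$y[hit])
  # pass 2: evaluate on a grid that maps the bounding box onto the full
  # width x height array, so the mask spans its box exactly
  xs <- seq(xr[1], xr[2], length.out = width)
  ys <- seq(yr[1], yr[2], length.out = height)
  bin <- outer(ys, xs, function(y, x) inside(x, y)) * 1
  # zero ring so the soft edge also decays at the array border
  padded <- matrix(0, height + 2, width + 2)
  padded[2:(height + 1), 2:(width + 1)] <- bin
  d <- EBImage::distmap(padded)[2:(height + 1), 2:(width + 1)]
  alpha <- ifelse(d >= edge_px, 1, 0.5 - 0.5 * cos(pi * d / edge_px))
  alpha <- orient_mask(alpha, orientation)
  structure(list(alpha = alpha, orientation = orientation,
                 anchor = c(x = (width + 1) / 2, y = (height + 1) / 2),
                 seed = seed),
            class = "scotoma_mask")
}

# axis flips; "h-flip" mirrors left-right (columns), "v-flip" top-bottom
orient_mask <- function(alpha, orientation) {
  switch(orientation,
         "original" = alpha,
         "h-flip" = alpha[, rev(seq_len(ncol(alpha))), drop = FALSE],
         "v-flip" = alpha[rev(seq_len(nrow(alpha))), , drop = FALSE],
         "hv-flip" = alpha[rev(seq_len(nrow(alpha))),
                           rev(seq_len(ncol(alpha))), drop = FALSE])
}

#' Re-orient an existing scotoma mask
#'
#' @param m a `scotoma_mask`.
#' @param orientation target orientation (see [build_scotoma_mask()]).
#' @return the mask with its alpha flipped accordingly.
#' @export
set_mask_orientation <- function(m, orientation = c("original", "h-flip",
                                                    "v-flip", "hv-flip")) {
  stopifnot(inherits(m, "scotoma_mask"))
  orientation <- match.arg(orientation)
  base <- orient_mask(m$alpha, m$orientation)  # flips are involutions
  m$alpha <- orient_mask(base, orientation)
  m$orientation <- orientation
  m
}

#' Bounding box of the non-zero alpha region
#'
#' @param m a `scotoma_mask`.
#' @return named vector `c(width, height)` in pixels.
#' @export
mask_bounding_box <- function(m) {
  stopifnot(inherits(m, "scotoma_mask"))
  nz <- which(m$alpha > 0, arr.ind = TRUE)
  c(width = diff(range(nz[, 2])) + 1L, height = diff(range(nz[, 1])) + 1L)
}

#' @export
print.scotoma_mask <- function(x, ...) {
  cat(sprintf("<scotoma_mask> %d x %d px, orientation %s, seed %s\n",
              ncol(x$alpha), nrow(x$alpha), x$orientation, x$seed))
  invisible(x)
}
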