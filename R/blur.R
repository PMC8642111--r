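#' Gaussian sigma realizing an FWHM amplitude cutoff
#'
#' For an isotropic Gaussian blur, the amplitude response is
#' `exp(-2 pi^2 sigma^2 f^2)`; solving for a response of one half at the
#' cutoff gives `sigma = sqrt(log(2)) / (sqrt(2) * pi * cutoff)`.
#'
#' @param cutoff spatial frequency (cycles/degree) at which the amplitude
#'   response should equal 0.5.
#' @return sigma in degrees of visual angle.
#' @examples
#' blur_sigma_deg(0.15) # 1.249 deg
#' @export
blur_sigma_deg <- function(cutoff) {
  if (any(cutoff <= 0)) stop("cutoff must be positive")
  sqrt(log(2)) / (sqrt(2) * pi * cutoff)
}

#' Gaussian low-pass filter a video frame
#'
#' Blurs a frame with an isotropic Gaussian whose amplitude response falls
#' to one half at `cutoff` cycles/degree (full width at half maximum
#' definition).  The sigma is converted to pixels with the horizontal
#' pixels-per-degree of the screen geometry; the screen is near-isotropic so
#' a single sigma keeps the filter isotropic.  The frame is reflectively
#' padded before filtering, which preserves mean luminance and avoids dark
#' vignettes at the frame edge.
#'
#' @param frame numeric matrix of pixel intensities (rows = y).
#' @param cutoff FWHM cutoff in cycles/degree (default 0.15).
#' @param g a [screen_geometry()].
#' @return blurred frame, same size.
#' @export
gaussian_lowpass_frame <- function(frame, cutoff = 0.15,
                                   g = screen_geometry()) {
  stopifnot(is.matrix(frame))
  if (cutoff <= 0) stop("cutoff must be positive")
  sigma <- blur_sigma_deg(cutoff) * pixels_per_degree(g)
  pad <- ceiling(3 * sigma)
  if (pad >= min(dim(frame)))
    stop("cutoff too low: blur kernel exceeds the frame size")
  fp <- reflect_pad(frame, pad)
  nr <- nrow(fp); nc <- ncol(fp)
  fy <- fft_freq(nr); fx <- fft_freq(nc)
  H <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, `+`))
  out <- Re(stats::fft(stats::fft(fp) * H, inverse = TRUE)) / (nr * nc)
  out[pad + seq_len(nrow(frame)), pad + seq_len(ncol(frame))]
}

# two-sided FFT frequencies in cycles/sample
fft_freq <- function(n) {
  k <- seq_len(n) - 1
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

reflect_pad <- function(m, pad) {
  idx <- function(n) {
    i <- c(rev(seq_len(pad) + 1), seq_len(n), n - seq_len(pad))
    pmin(pmax(i, 1L), n)
  }
  m[idx(nrow(m)), idx(ncol(m))]
}

#' Measure the half-amplitude cutoff of the blur stage
#'
#' Probes [gaussian_lowpass_frame()] with sinusoidal gratings over a sweep
#' of spatial frequencies, measures the output/input amplitude ratio of
#' each, and interpolates the frequency at which the ratio crosses 0.5.
#' Serves as an end-to-end calibration check of the blur filter.
#'
#' @param cutoff nominal FWHM cutoff handed to the filter, cycles/degree.
#' @param freqs grating frequencies to probe, cycles/degree.
#' @param g a [screen_geometry()].
#' @param size probe frame size in pixels (square).
#' @return list with `cutoff_measured` (cycles/degree) and the sweep table
#'   `response` (`freq`, `ratio`).
#' @export
measure_blur_cutoff <- function(cutoff = 0.15,
                                freqs = seq(0.08, 0.26, by = 0.02),
                                g = screen_geometry(), size = 512) {
  ppd <- pixels_per_degree(g)
  ratio <- vapply(freqs, function(f) {
    gr <- grating_frame(f, size, ppd)
    bl <- gaussian_lowpass_frame(gr, cutoff, g)
    core <- seq(round(size * 0.3), round(size * 0.7))  # avoid pad edges
    amp_in <- (max(gr[core, core]) - min(gr[core, core])) / 2
    amp_out <- (max(bl[core, core]) - min(bl[core, core])) / 2
    amp_out / amp_in
  }, numeric(1))
  cutoff_measured <- if (length(freqs) >= 2)
    stats::approx(ratio, freqs, xout = 0.5, ties = mean)$y
  else NA_real_
  list(cutoff_measured = cutoff_measured,
       response = data.frame(freq = freqs, ratio = ratio))
}

# horizontal sinusoidal grating at f cycles/degree, intensities in [0, 1]
grating_frame <- function(f, size, ppd) {
  x <- seq_len(size) / ppd
  matrix(rep(0.5 + 0.5 * sin(2 * pi * f * x), each = size), size, size)
}
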