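#' Audiogram container and the moderate-loss preset
#'
#' An audiogram lists hearing thresholds (dB HL) at the six octave
#' audiometric frequencies 250 Hz to 8 kHz.  `audiogram_n3()` returns the
#' moderate sensorineural loss used throughout the package: 40, 40, 45, 54,
#' 62, and 70 dB HL at 250, 500, 1000, 2000, 4000, and 8000 Hz.
#'
#' @param freqs audiometric frequencies, Hz.
#' @param thresholds_hl thresholds in dB HL, same length as `freqs`,
#'   within \[-10, 120\].
#' @return an `audiogram` object (data frame with `freq` and `threshold_hl`).
#' @export
audiogram <- function(freqs = c(250, 500, 1000, 2000, 4000, 8000),
                      thresholds_hl) {
  if (length(freqs) != length(thresholds_hl))
    stop("freqs and thresholds_hl must have the same length")
  if (any(thresholds_hl < -10 | thresholds_hl > 120))
    stop("thresholds must lie within [-10, 120] dB HL")
  structure(data.frame(freq = freqs, threshold_hl = thresholds_hl),
            class = c("audiogram", "data.frame"))
}

#' @rdname audiogram
#' @export
audiogram_n3 <- function() {
  audiogram(thresholds_hl = c(40, 40, 45, 54, 62, 70))
}

#' Categorical loudness functions for normal and impaired hearing
#'
#' Builds the level-to-loudness maps used by the loudness stage of the
#' hearing-impairment simulation, on the categorical-unit (CU) scale from 0
#' (inaudible) to `max_cu` (uncomfortably loud).  Both maps are
#' piecewise-linear in dB: the normal-hearing curve rises from 0 CU at the
#' normal threshold to `max_cu` at the common anchor level; the impaired
#' curve rises from 0 CU at the band's simulated (elevated) threshold to
#' `max_cu` at the same anchor.  The steeper impaired slope is loudness
#' recruitment: loudness catches up with normal at high levels.
#'
#' dB HL is converted to dB SPL with a configurable RETSPL offset per band;
#' the default is all zeros (HL treated as SPL).
#'
#' @param audiogram an [audiogram()] at the six octave frequencies.
#' @param anchor_spl level (dB SPL) where both curves reach `max_cu`
#'   (default 105, the uncomfortable-loudness anchor).
#' @param max_cu top of the categorical scale (default 50).
#' @param retspl per-band dB offsets converting HL to SPL (default zeros).
#' @return a `loudness_functions` object with vectorized members
#'   `nh_cu(level, band)`, `hi_cu(level, band)`, `nh_level(cu, band)`.
#' @export
loudness_functions <- function(audiogram = audiogram_n3(),
                               anchor_spl = 105, max_cu = 50,
                               retspl = rep(0, nrow(audiogram))) {
  stopifnot(inherits(audiogram, "audiogram"))
  if (length(retspl) != nrow(audiogram))
    stop("retspl must have one offset per audiogram frequency")
  nh_thr <- retspl                                  # 0 dB HL in SPL
  hi_thr <- audiogram$threshold_hl + retspl
  if (any(hi_thr >= anchor_spl))
    stop("simulated thresholds must lie below the anchor level")
  cu_from <- function(level, thr) {
    pmin(pmax((level - thr) / (anchor_spl - thr), 0), 1) * max_cu
  }
  structure(
    list(
      freqs = audiogram$freq, nh_thr = nh_thr, hi_thr = hi_thr,
      anchor_spl = anchor_spl, max_cu = max_cu,
      nh_cu = function(level, band) cu_from(level, nh_thr[band]),
      hi_cu = function(level, band) cu_from(level, hi_thr[band]),
      nh_level = function(cu, band)
        nh_thr[band] + (anchor_spl - nh_thr[band]) * cu / max_cu),
    class = "loudness_functions")
}

#' Level mapping of the recruitment stage
#'
#' The per-band input-output level function applied by
#' [loudness_transform()]: the input level is read off the impaired loudness
#' curve and the output level is the level at which a normal listener
#' reaches the same loudness, clamped so that no band is ever amplified.
#' An input exactly at the simulated threshold maps to the normal threshold
#' of audibility (0 CU); below it, the expansive recruitment slope
#' continues downward, so sub-threshold inputs emerge strictly below normal
#' audibility.
#'
#' @param level_in input band level, dB SPL (vectorized).
#' @param band octave-band index (1 = 250 Hz ... 6 = 8 kHz).
#' @param lf a [loudness_functions()] object.
#' @return output band level, dB SPL.
#' @export
loudness_map_level <- function(level_in, band, lf) {
  stopifnot(inherits(lf, "loudness_functions"))
  nh_thr <- lf$nh_thr[band]
  hi_thr <- lf$hi_thr[band]
  slope <- (lf$anchor_spl - nh_thr) / (lf$anchor_spl - hi_thr)
  raw <- ifelse(level_in > hi_thr,
                lf$nh_level(lf$hi_cu(level_in, band), band),
                nh_thr + slope * (level_in - hi_thr))
  pmin(level_in, raw)
}

# geometric-midpoint octave band edges; bins outside the span take the
# nearest band (band 1 below, band 6 above)
octave_band_of <- function(freq_hz, band_freqs) {
  edges <- sqrt(band_freqs[-length(band_freqs)] * band_freqs[-1])
  findInterval(freq_hz, edges) + 1L
}

#' Threshold and recruitment loudness transform
#'
#' Short-time spectral attenuation implementing elevated audiometric
#' thresholds and loudness recruitment.  The signal is cut into Hann
#' windowed frames (about 23 ms, 50% overlap), each frame is Fourier
#' transformed and split into six octave-spaced channels between 250 Hz and
#' 8 kHz, and each channel's level is attenuated expansively so that a
#' normal listener's loudness of the output matches the impaired loudness of
#' the input (see [loudness_map_level()]).  Frames are reassembled by
#' overlap-add, which reconstructs the input exactly when all gains are
#' unity.
#'
#' @param x a calibrated `audio_signal`.
#' @param audiogram an [audiogram()]; defaults to the moderate-loss preset.
#' @param lf optional [loudness_functions()]; built from `audiogram` when
#'   missing.
#' @param frame_ms approximate analysis frame length in ms (rounded to a
#'   power of two samples; default 23).
#' @return an `audio_signal` of the same length, rate, and calibration.
#' @export
loudness_transform <- function(x, audiogram = audiogram_n3(), lf = NULL,
                               frame_ms = 23) {
  stopifnot(inherits(x, "audio_signal"))
  if (is.null(x$calibration_spl) || !is.finite(x$calibration_spl))
    stop("input must be calibrated (calibration_spl set)")
  if (is.null(lf)) lf <- loudness_functions(audiogram)
  n <- length(x$samples)
  nfft <- 2^round(log2(x$rate * frame_ms / 1000))
  hop <- nfft %/% 2
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft)  # periodic Hann, COLA at 50%
  freqs <- (seq_len(nfft) - 1) * x$rate / nfft
  freqs[freqs > x$rate / 2] <- x$rate - freqs[freqs > x$rate / 2]  # fold negatives
  band_of <- octave_band_of(freqs, lf$freqs)
  n_bands <- length(lf$freqs)
  if (length(unique(band_of[freqs >= 250 & freqs <= 8000])) < n_bands)
    stop("sampling rate leaves an octave band with no FFT bins")
  # frame band power -> dB SPL calibration: P_band / ref_rms^2, with the
  # window energy normalization making a stationary signal's summed frame
  # band powers equal its mean power
  wnorm <- nfft * sum(w^2)
  ref_p <- x$ref_rms^2
  pad <- c(numeric(hop), x$samples, numeric(nfft))
  y <- numeric(length(pad))
  starts <- seq(1, length(pad) - nfft + 1, by = hop)
  for (s in starts) {
    fr <- pad[s:(s + nfft - 1)] * w
    X <- stats::fft(fr)
    p_band <- vapply(seq_len(n_bands), function(b)
      sum(Mod(X[band_of == b])^2) / wnorm, numeric(1))
    gain_db <- numeric(n_bands)
    nz <- p_band > 0
    if (any(nz)) {
      l_in <- x$calibration_spl + 10 * log10(p_band[nz] / ref_p)
      l_out <- loudness_map_level(l_in, which(nz), lf)
      gain_db[nz] <- l_out - l_in
    }
    g <- 10^(gain_db / 20)
    yfr <- Re(stats::fft(X * g[band_of], inverse = TRUE)) / nfft
    y[s:(s + nfft - 1)] <- y[s:(s + nfft - 1)] + yfr
  }
  audio_signal(y[(hop + 1):(hop + n)], x$rate,
               calibration_spl = x$calibration_spl, ref_rms = x$ref_rms)
}

#' Measure the simulated audiometric threshold at a frequency
#'
#' Runs calibrated pure tones through [loudness_transform()] and bisects for
#' the lowest presentation level at which the output is still audible, i.e.
#' its band level maps to more than zero categorical units on the
#' normal-hearing loudness function.  Under the default all-zero RETSPL the
#' returned level is in dB HL.
#'
#' @param freq probe frequency, Hz.
#' @param audiogram an [audiogram()].
#' @param rate sampling rate for the probe tones, Hz.
#' @param tol bisection tolerance, dB.
#' @return threshold level in dB HL.
#' @export
simulated_threshold <- function(freq, audiogram = audiogram_n3(),
                                rate = 22050, tol = 0.05) {
  lf <- loudness_functions(audiogram)
  band <- octave_band_of(freq, lf$freqs)
  audible <- function(level) {
    y <- loudness_transform(pure_tone(freq, level, duration = 0.25, rate),
                            audiogram, lf)
    l_out <- band_level(y, band, lf)
    is.finite(l_out) && lf$nh_cu(l_out, band) > 1e-6
  }
  lo <- -10; hi <- 119
  if (audible(lo)) return(lo)
  if (!audible(hi)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (audible(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Long-term octave-band level of a calibrated signal
#'
#' @param x an `audio_signal`.
#' @param band octave-band index (1-6).
#' @param lf a [loudness_functions()] object (for the band grid).
#' @return band level in dB SPL (`-Inf` for a silent band).
#' @export
band_level <- function(x, band, lf = loudness_functions()) {
  n <- length(x$samples)
  X <- stats::fft(x$samples)
  freqs <- (seq_len(n) - 1) * x$rate / n
  freqs[freqs > x$rate / 2] <- x$rate - freqs[freqs > x$rate / 2]
  sel <- octave_band_of(freqs, lf$freqs) == band
  p <- sum(Mod(X[sel])^2) / n^2
  x$calibration_spl + 10 * log10(p / x$ref_rms^2)
}

#' Full sensorineural hearing-impairment simulation
#'
#' Chains the three stages of the simulation: impaired-filter envelope
#' imposition ([impose_impaired_envelopes()]), threshold/recruitment
#' loudness mapping ([loudness_transform()]), and RMS equalization back to
#' the intact input level ([rms_equalize()]).  Deterministic: no randomness
#' anywhere in the chain.
#'
#' @param x a calibrated `audio_signal`.
#' @param audiogram an [audiogram()]; default the moderate-loss preset.
#' @param n_iter envelope-imposition iterations (default 10).
#' @param bandwidth_scale auditory-filter broadening factor (default 2).
#' @param frame_ms loudness analysis frame length, ms.
#' @return degraded `audio_signal` with the same RMS as the input.
#' @export
simulate_hearing_impairment <- function(x, audiogram = audiogram_n3(),
                                        n_iter = 10, bandwidth_scale = 2,
                                        frame_ms = 23) {
  y <- impose_impaired_envelopes(x, n_iter = n_iter,
                                 bandwidth_scale = bandwidth_scale)
  y <- loudness_transform(y, audiogram, frame_ms = frame_ms)
  rms_equalize(y, x)
}
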