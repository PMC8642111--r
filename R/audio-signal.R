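#' Calibrated audio signal
#'
#' A mono waveform together with its sample rate and a level calibration.
#' The calibration states the sound pressure level (dB SPL) that corresponds
#' to a stated reference digital RMS, so that band levels computed from the
#' digital samples can be expressed on the physical dB SPL scale.  By default
#' the reference RMS is the signal's own long-term RMS, matching the common
#' practice of presenting stimuli "at a long-term RMS average of X dB SPL".
#'
#' @param samples numeric vector of samples, nominally within full scale
#'   \[-1, 1\].
#' @param rate sampling rate in Hz.
#' @param calibration_spl dB SPL corresponding to `ref_rms` (default 65).
#' @param ref_rms digital RMS that corresponds to `calibration_spl`.
#'   Defaults to the long-term RMS of `samples`.
#' @return an object of class `audio_signal`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 1000 * seq(0, 0.1, by = 1 / 44100)), 44100)
#' rms_level(x)
#' @export
audio_signal <- function(samples, rate, calibration_spl = 65,
                         ref_rms = NULL) {
  stopifnot(is.numeric(samples), length(samples) > 0)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number")
  if (!all(is.finite(samples)))
    stop("`samples` must be finite")
  if (!is.finite(calibration_spl))
    stop("`calibration_spl` must be finite")
  if (is.null(ref_rms)) ref_rms <- rms(samples)
  structure(
    list(samples = as.numeric(samples), rate = rate,
         calibration_spl = calibration_spl, ref_rms = ref_rms),
    class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal> %d samples @ %g Hz (%.3f s), RMS %.4g (%g dB SPL at RMS %.4g)\n",
    length(x$samples), x$rate, length(x$samples) / x$rate,
    rms(x$samples), x$calibration_spl, x$ref_rms))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

as_audio_samples <- function(x) {
  if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
}

#' Root-mean-square of a waveform
#'
#' @param x numeric vector or `audio_signal`.
#' @return scalar RMS.
#' @export
rms <- function(x) {
  s <- as_audio_samples(x)
  sqrt(mean(s^2))
}

#' Long-term level of a calibrated signal in dB SPL
#'
#' @param x an `audio_signal`.
#' @return level in dB SPL implied by the signal's calibration.
#' @export
rms_level <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  if (rms(x) == 0) stop("silent signal has no level")
  x$calibration_spl + 20 * log10(rms(x) / x$ref_rms)
}

#' Calibrated pure tone
#'
#' Convenience constructor for a sinusoid whose long-term level is
#' `level_spl` under the returned signal's calibration.  Useful for probing
#' the loudness stage (e.g. audiometric threshold sweeps).
#'
#' @param freq tone frequency, Hz.
#' @param level_spl presentation level in dB SPL (equivalently dB HL under
#'   the default all-zero RETSPL convention).
#' @param duration seconds.
#' @param rate sampling rate, Hz.
#' @return an `audio_signal` whose `rms_level()` equals `level_spl`.
#' @export
pure_tone <- function(freq, level_spl, duration = 0.5, rate = 22050) {
  t <- seq(0, duration, by = 1 / rate)
  s <- sin(2 * pi * freq * t)
  audio_signal(s, rate, calibration_spl = level_spl, ref_rms = rms(s))
}

#' Match the RMS of a signal to a reference
#'
#' Scales `y` by a single factor so that its RMS equals the RMS of `ref`.
#' The waveform shape is unchanged; only the overall level moves.  Applied as
#' the final stage of the hearing-impairment simulation so that degraded and
#' intact stimuli are presented at the same long-term level.
#'
#' @param y `audio_signal` to rescale.
#' @param ref reference `audio_signal` (or numeric vector).
#' @return `y` rescaled; calibration metadata is carried over from `y`.
#' @export
rms_equalize <- function(y, ref) {
  stopifnot(inherits(y, "audio_signal"))
  r_ref <- rms(ref)
  if (r_ref <= 0) stop("reference signal is silent")
  r_y <- rms(y)
  if (r_y == 0) stop("cannot equalize silence")
  audio_signal(y$samples * (r_ref / r_y), y$rate,
               calibration_spl = y$calibration_spl, ref_rms = y$ref_rms)
}
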