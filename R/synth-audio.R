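#' Generate speech-shaped amplitude-modulated noise
#'
#' Synthesizes a broadband noise with the gross spectro-temporal statistics
#' of pseudo-speech: a flat spectrum up to 500 Hz falling at -6 dB/octave
#' above it, amplitude-modulated by a slow lognormal envelope whose
#' modulation energy lies in the syllabic 2-8 Hz range.  The signal stands
#' in for spoken emotion portrayals when exercising the hearing-impairment
#' simulation.  Deterministic for a fixed seed.
#'
#' @param duration seconds, within the 1-7 s range of the stimulus set
#'   (default 2.5, the mean stimulus duration).
#' @param rate sampling rate, Hz (must carry the 10 kHz filterbank span).
#' @param seed RNG seed.
#' @param mod_depth depth of the lognormal amplitude modulation (log-SD
#'   units; 0 disables modulation).
#' @param tilt spectral slope above the corner frequency, dB/octave.
#' @param corner_hz corner frequency of the spectral tilt, Hz.
#' @param calibration_spl presentation level of the result, dB SPL.
#' @return an `audio_signal`.
#' @export
gen_speech_like_audio <- function(duration = 2.5, rate = 22050, seed = 1,
                                  mod_depth = 0.5, tilt = -6,
                                  corner_hz = 500, calibration_spl = 65) {
  if (duration < 1 || duration > 7)
    stop("duration must lie within the 1-7 s stimulus range")
  n <- round(duration * rate)
  withr::with_seed(seed, {
    noise <- stats::rnorm(n)
    gmod <- stats::rnorm(n)
  })
  # spectral tilt: amplitude scaling (f/corner)^(tilt/6.02) above the corner
  X <- stats::fft(noise)
  f <- (seq_len(n) - 1) * rate / n
  f[f > rate / 2] <- rate - f[f > rate / 2]
  shape <- ifelse(f <= corner_hz, 1,
                  (f / corner_hz)^(tilt / (20 * log10(2))))
  carrier <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  # syllabic-band lognormal envelope: bandpass 2-8 Hz in the log domain
  env <- if (mod_depth > 0) {
    G <- stats::fft(gmod)
    band <- f >= 2 & f <= 8
    gslow <- Re(stats::fft(G * band, inverse = TRUE)) / n
    gslow <- gslow / stats::sd(gslow)
    exp(mod_depth * gslow)
  } else rep(1, n)
  s <- carrier * env
  s <- s / max(abs(s)) * 0.5
  audio_signal(s, rate, calibration_spl = calibration_spl)
}
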