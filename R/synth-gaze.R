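#' Default gaze-generator parameters per age group and video state
#'
#' Mean saccadic amplitudes use the group means reported for intact versus
#' degraded video (young: 2.83 and 6.54 degrees; older: 1.58 and 2.78
#' degrees).  Absolute fixation-duration levels are not published, so the
#' defaults place the young intact-video mean at a typical 450 ms and apply
#' the reported group difference (126 ms shorter in older adults) and the
#' reported degradation adaptations (young shorten by 225 ms under degraded
#' video, older by 11 ms).
#'
#' @return data frame with `age_group`, `video`, `mean_fix_ms`,
#'   `mean_sacc_deg`, `blink_rate_hz`.
#' @export
default_gaze_params <- function() {
  data.frame(
    age_group = rep(c("young", "older"), each = 2),
    video = rep(c("intact", "degraded"), 2),
    mean_fix_ms = c(450, 225, 324, 313),
    mean_sacc_deg = c(2.83, 6.54, 1.58, 2.78),
    blink_rate_hz = 0.1)
}

#' Generate a synthetic fixation-saccade-blink event stream
#'
#' Simulates the parsed gaze events of one trial as an alternating renewal
#' process: fixation durations and saccadic amplitudes are Gamma
#' distributed around the supplied means (shape fixed, so the mean is the
#' single free location parameter), saccade landing positions are biased
#' toward the face center when the video is intact and away from it (a
#' compensatory eccentric-viewing strategy) when the video is degraded, and
#' blinks arrive as a Poisson process with lognormal durations.
#' Deterministic for a fixed seed.
#'
#' @param duration_ms trial duration (>= 1000 ms).
#' @param mean_fix_ms mean fixation duration, ms.
#' @param mean_sacc_deg mean saccadic amplitude, degrees.
#' @param blink_rate_hz blink rate, events/s.
#' @param video `"intact"` or `"degraded"` (controls the landing bias).
#' @param seed RNG seed.
#' @param g a [screen_geometry()].
#' @param face_center `c(x, y)` pixels; landing-bias target.
#' @param shape Gamma shape for durations and amplitudes (default 4).
#' @param blink_meanlog,blink_sdlog lognormal blink-duration parameters
#'   (default meanlog `log(120)` ms, sdlog 0.4).
#' @return gaze event table: `kind`, `t_on`, `t_off`, `x`, `y`,
#'   `amplitude` (degrees, saccades only), ordered in time.
#' @export
gen_gaze_trace <- function(duration_ms = 1500, mean_fix_ms = 450,
                           mean_sacc_deg = 2.83, blink_rate_hz = 0.1,
                           video = c("intact", "degraded"), seed = 1,
                           g = screen_geometry(),
                           face_center = c(960, 420), shape = 4,
                           blink_meanlog = log(120), blink_sdlog = 0.4) {
  if (duration_ms < 1000) stop("trial must last at least 1000 ms")
  video <- match.arg(video)
  ppd <- pixels_per_degree(g)
  withr::with_seed(seed, {
    pos <- face_center + stats::rnorm(2, 0, 0.5 * ppd)
    t <- 0
    rows <- list()
    while (t < duration_ms) {
      fdur <- stats::rgamma(1, shape = shape, scale = mean_fix_ms / shape)
      rows[[length(rows) + 1]] <- data.frame(
        kind = "fixation", t_on = t, t_off = t + fdur,
        x = pos[1], y = pos[2], amplitude = NA_real_)
      t <- t + fdur
      amp <- stats::rgamma(1, shape = shape, scale = mean_sacc_deg / shape)
      # landing: toward the face center for intact video, away under
      # degradation (plus angular jitter)
      to_center <- atan2(face_center[2] - pos[2], face_center[1] - pos[1])
      dir <- if (video == "intact") to_center else to_center + pi
      dir <- dir + stats::rnorm(1, 0, pi / 3)
      sdur <- 20 + 2.2 * amp                # main-sequence-like duration
      new_pos <- pos + amp * ppd * c(cos(dir), sin(dir))
      new_pos[1] <- min(max(new_pos[1], 1), g$width_px)
      new_pos[2] <- min(max(new_pos[2], 1), g$height_px)
      rows[[length(rows) + 1]] <- data.frame(
        kind = "saccade", t_on = t, t_off = t + sdur,
        x = new_pos[1], y = new_pos[2], amplitude = amp)
      pos <- new_pos
      t <- t + sdur
    }
    ev <- do.call(rbind, rows)
    ev <- ev[ev$t_on < duration_ms, , drop = FALSE]
    ev$t_off <- pmin(ev$t_off, duration_ms)
    n_blinks <- stats::rpois(1, blink_rate_hz * duration_ms / 1000)
    if (n_blinks > 0) {
      b_on <- sort(stats::runif(n_blinks, 0, duration_ms))
      b_dur <- stats::rlnorm(n_blinks, blink_meanlog, blink_sdlog)
      ev <- rbind(ev, data.frame(
        kind = "blink", t_on = b_on,
        t_off = pmin(b_on + b_dur, duration_ms),
        x = NA_real_, y = NA_real_, amplitude = NA_real_))
    }
  })
  ev <- ev[order(ev$t_on), ]
  rownames(ev) <- NULL
  ev
}

#' Generate gaze event tables for a set of trials
#'
#' Applies [gen_gaze_trace()] per trial with group- and condition-specific
#' parameters looked up in a parameter table, deriving one child seed per
#' trial so the whole set is reproducible from a single seed.
#'
#' @param trials data frame with `trial`, `age_group`, and `condition` (or
#'   a `video` column directly).
#' @param params parameter table as in [default_gaze_params()].
#' @param seed master seed.
#' @param duration_ms trial duration, ms.
#' @param ... passed on to [gen_gaze_trace()].
#' @return gaze event table with a `trial` column prepended.
#' @export
gen_gaze_set <- function(trials, params = default_gaze_params(), seed = 1,
                         duration_ms = 1500, ...) {
  if (is.null(trials$video)) {
    cs <- condition_set()
    trials$video <- cs$video[match(trials$condition, cs$condition)]
  }
  if (any(trials$video == "absent"))
    stop("gaze is only generated for trials with video present")
  out <- lapply(seq_len(nrow(trials)), function(i) {
    p <- params[params$age_group == trials$age_group[i] &
                  params$video == trials$video[i], ]
    if (nrow(p) != 1) stop("no gaze parameters for trial ", trials$trial[i])
    ev <- gen_gaze_trace(duration_ms = duration_ms,
                         mean_fix_ms = p$mean_fix_ms,
                         mean_sacc_deg = p$mean_sacc_deg,
                         blink_rate_hz = p$blink_rate_hz,
                         video = trials$video[i],
                         seed = (seed * 10007L + i) %% .Machine$integer.max,
                         ...)
    cbind(trial = trials$trial[i], ev)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
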