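#' Window gaze events to the analysis interval after stimulus onset
#'
#' Restricts a gaze event table to the first `window_ms` (default 1000 ms,
#' the duration of the shortest stimulus) after stimulus onset.  Events
#' entirely outside the window are dropped; events straddling a boundary
#' are kept with their onset/offset truncated at the boundary, so counted
#' durations never exceed the time actually spent inside the window.
#'
#' @param g gaze event table: data frame with `kind`
#'   (`fixation`/`saccade`/`blink`), `t_on`, `t_off` (ms, relative to the
#'   recording), plus `x`, `y` (fixations) and `amplitude` (saccades).
#' @param stim_on stimulus onset time, ms.
#' @param window_ms analysis window length, ms.
#' @param truncate if `FALSE`, straddling events are kept whole instead of
#'   truncated.
#' @return the windowed event table, times re-expressed relative to onset.
#' @export
window_trial <- function(g, stim_on = 0, window_ms = 1000, truncate = TRUE) {
  end <- stim_on + window_ms
  keep <- g$t_off > stim_on & g$t_on < end
  g <- g[keep, , drop = FALSE]
  if (truncate && nrow(g) > 0) {
    g$t_on <- pmax(g$t_on, stim_on)
    g$t_off <- pmin(g$t_off, end)
  }
  if (nrow(g) > 0) {
    g$t_on <- g$t_on - stim_on
    g$t_off <- g$t_off - stim_on
  }
  g
}

#' Discard trials containing a long blink
#'
#' Drops every trial whose (windowed) gaze events include a single blink
#' longer than `max_blink_ms` (strictly longer; a blink of exactly the
#' threshold is tolerated, and several shorter blinks never trigger the
#' exclusion).
#'
#' @param g gaze event table for one or more trials, with a `trial` column.
#' @param max_blink_ms blink-duration threshold, ms (default 300).
#' @return the table without the excluded trials; attribute
#'   `"excluded_trials"` lists the dropped trial ids.
#' @export
exclude_blink_trials <- function(g, max_blink_ms = 300) {
  dur <- g$t_off - g$t_on
  bad <- unique(g$trial[g$kind == "blink" & dur > max_blink_ms])
  out <- g[!g$trial %in% bad, , drop = FALSE]
  attr(out, "excluded_trials") <- bad
  out
}

#' Filter out implausibly large saccades
#'
#' Removes saccade events whose amplitude exceeds the maximum (strictly
#' larger than; default the display diagonal of 49.6 degrees).  Fixations
#' and blinks pass through untouched.
#'
#' @param g gaze event table.
#' @param max_amplitude amplitude ceiling in degrees.
#' @return filtered table.
#' @export
filter_saccades <- function(g, max_amplitude = display_diagonal_deg()) {
  if (max_amplitude <= 0) stop("max_amplitude must be positive")
  drop <- g$kind == "saccade" & !is.na(g$amplitude) &
    g$amplitude > max_amplitude
  g[!drop, , drop = FALSE]
}

#' Keep only trials answered correctly
#'
#' Restricts gaze data to trials with a correct behavioral response, the
#' default for analyzing gaze behavior leading up to correct recognition.
#' Set `only_correct = FALSE` to keep everything (for checking that
#' inclusion does not change conclusions).
#'
#' @param g gaze event table with a `trial` column.
#' @param responses data frame with `trial` and logical `correct`.
#' @param only_correct switch for the filter.
#' @return filtered table.
#' @export
keep_correct_trials <- function(g, responses, only_correct = TRUE) {
  if (!all(g$trial %in% responses$trial))
    stop("unmatched trial id(s): ",
         paste(utils::head(setdiff(g$trial, responses$trial)), collapse = ", "))
  if (!only_correct) return(g)
  ok <- responses$trial[responses$correct]
  g[g$trial %in% ok, , drop = FALSE]
}

#' Summarize fixation durations and saccadic amplitudes per trial
#'
#' @param g windowed, filtered gaze event table with a `trial` column.
#' @return data frame with one row per trial: `n_fixations`,
#'   `mean_fix_dur` (ms), `n_saccades`, `mean_sacc_amp` (deg).
#' @export
gaze_trial_stats <- function(g) {
  trials <- unique(g$trial)
  out <- do.call(rbind, lapply(trials, function(tr) {
    e <- g[g$trial == tr, ]
    fx <- e[e$kind == "fixation", ]
    sc <- e[e$kind == "saccade", ]
    data.frame(trial = tr, n_fixations = nrow(fx),
               mean_fix_dur = if (nrow(fx)) mean(fx$t_off - fx$t_on) else NA_real_,
               n_saccades = nrow(sc),
               mean_sacc_amp = if (nrow(sc)) mean(sc$amplitude) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
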