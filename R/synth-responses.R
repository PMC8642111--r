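#' Default response-accuracy parameters per age group and condition
#'
#' Probability of a correct response in each cell of the design.  The
#' defaults follow the qualitative ordering of the behavioral results:
#' audio-only below video-only below audiovisual, degraded at or below
#' intact, and older adults about 0.12 below young adults throughout.
#'
#' @return data frame with `age_group`, `condition`, `p_correct`.
#' @export
default_accuracy_params <- function() {
  young <- c(AV = 0.62, AdV = 0.55, A = 0.42, dAV = 0.58, dAdV = 0.45,
             dA = 0.35, V = 0.52, dV = 0.42)
  data.frame(
    age_group = rep(c("young", "older"), each = 8),
    condition = rep(names(young), 2),
    p_correct = c(young, pmax(young - 0.12, 0.05)))
}

#' Fill a trial schedule with confusion-structured responses
#'
#' Simulates the 12-alternative forced choice: each trial is answered
#' correctly with the cell's configured probability; errors are drawn from
#' the remaining emotions with weights that decay with valence-arousal
#' distance (confusions stay mostly within the quadrant of the true
#' emotion) multiplied by a per-emotion response-bias vector.  A non-uniform
#' bias makes some responses over-used, which is exactly the situation the
#' unbiased hit-rate corrects for.  Deterministic for a fixed seed.
#'
#' Each participant additionally carries a stable ability offset (normal on
#' the log-odds scale, SD `participant_sd`), giving the between-participant
#' heterogeneity that the random intercepts of the accuracy models estimate.
#'
#' @param schedule trial table from [build_schedule()].
#' @param accuracy table as in [default_accuracy_params()].
#' @param bias named numeric vector of response-bias weights over the 12
#'   emotions (default all 1).
#' @param confusion_decay weight multiplier per step of valence-arousal
#'   distance (0..2 steps; default 0.35).
#' @param participant_sd SD of the per-participant log-odds ability offset
#'   (default 0.3; 0 disables heterogeneity).
#' @param seed RNG seed.
#' @return the schedule with `response` and `correct` filled in.
#' @export
gen_responses <- function(schedule, accuracy = default_accuracy_params(),
                          bias = NULL, confusion_decay = 0.35,
                          participant_sd = 0.3, seed = 1) {
  emo <- emotion_set()
  if (is.null(bias)) bias <- stats::setNames(rep(1, 12), emo$emotion)
  if (!all(emo$emotion %in% names(bias)))
    stop("bias must name every emotion")
  p_cell <- accuracy$p_correct[
    match(paste(schedule$age_group, schedule$condition),
          paste(accuracy$age_group, accuracy$condition))]
  if (any(is.na(p_cell)))
    stop("accuracy table lacks some age_group x condition cells")
  # valence-arousal distance between emotion categories: 0 same quadrant,
  # 1 one axis differs, 2 both differ
  dist <- outer(seq_len(12), seq_len(12), function(i, j)
    (emo$valence[i] != emo$valence[j]) + (emo$arousal[i] != emo$arousal[j]))
  ppts <- unique(schedule$participant)
  withr::with_seed(seed, {
    ability <- stats::setNames(stats::rnorm(length(ppts), 0, participant_sd),
                               ppts)
    p_trial <- stats::plogis(stats::qlogis(pmin(pmax(p_cell, 1e-6), 1 - 1e-6)) +
                               ability[schedule$participant])
    p_trial[p_cell %in% c(0, 1)] <- p_cell[p_cell %in% c(0, 1)]  # exact edges
    resp <- vapply(seq_len(nrow(schedule)), function(i) {
      true <- match(schedule$emotion[i], emo$emotion)
      if (stats::runif(1) < p_trial[i]) return(emo$emotion[true])
      w <- confusion_decay^dist[true, ] * bias[emo$emotion]
      w[true] <- 0
      sample(emo$emotion, 1, prob = w)
    }, character(1))
  })
  schedule$response <- resp
  schedule$correct <- schedule$response == schedule$emotion
  schedule
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: builds the schedule for `n_young` young and
#' `n_older` older participants, optionally shifts the older group's
#' accuracy by `age_effect`, and fills in responses.  Used for end-to-end
#' parameter-recovery checks of the behavioral pipeline.
#'
#' @param n_young,n_older group sizes (defaults 24 and 21, the study
#'   groups).
#' @param age_effect amount subtracted from the young accuracy to get the
#'   older accuracy (overrides the default table when not `NULL`).
#' @param seed RNG seed.
#' @param ... passed to [gen_responses()].
#' @return completed trial table.
#' @export
gen_study <- function(n_young = 24, n_older = 21, age_effect = NULL,
                      seed = 1, ...) {
  participants <- data.frame(
    participant = sprintf("%s%02d", rep(c("y", "o"), c(n_young, n_older)),
                          c(seq_len(n_young), seq_len(n_older))),
    age_group = rep(c("young", "older"), c(n_young, n_older)))
  sched <- build_schedule(participants, seed = seed)
  acc <- default_accuracy_params()
  if (!is.null(age_effect)) {
    young <- acc$p_correct[acc$age_group == "young"]
    acc$p_correct[acc$age_group == "older"] <-
      pmin(pmax(young - age_effect, 0.02), 1)
  }
  gen_responses(sched, accuracy = acc, seed = seed + 1, ...)
}
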