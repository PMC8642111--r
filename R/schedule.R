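#' Emotion and condition sets of the recognition experiment
#'
#' `emotion_set()` returns the 12 emotion categories with their
#' valence-arousal quadrant (three per quadrant); `condition_set()` returns
#' the eight presentation conditions, crossing intact (A, V), degraded (dA,
#' dV), and absent states of the audio and video modalities.
#'
#' @return `emotion_set()`: data frame with `emotion`, `valence`
#'   (`positive`/`negative`), `arousal` (`high`/`low`); `condition_set()`:
#'   data frame with `condition`, `audio`, `video`
#'   (`intact`/`degraded`/`absent`).
#' @export
emotion_set <- function() {
  data.frame(
    emotion = c("Amusement", "Joy", "Pride", "Fear", "Despair", "Anger",
                "Pleasure", "Relief", "Interest",
                "Irritation", "Anxiety", "Sadness"),
    valence = rep(c("positive", "negative", "positive", "negative"),
                  each = 3),
    arousal = rep(c("high", "low"), each = 6))
}

#' @rdname emotion_set
#' @export
condition_set <- function() {
  data.frame(
    condition = c("AV", "AdV", "A", "dAV", "dAdV", "dA", "V", "dV"),
    audio = c("intact", "intact", "intact", "degraded", "degraded",
              "degraded", "absent", "absent"),
    video = c("intact", "degraded", "absent", "intact", "degraded",
              "absent", "intact", "degraded"))
}

#' Balanced Latin square
#'
#' Standard balanced Latin square of even order n by the row-column
#' construction (first row 1, 2, n, 3, n-1, ...; subsequent rows shift by
#' one): every condition precedes and follows every other equally often
#' across the n row orders.
#'
#' @param n order (must be even for the balanced construction).
#' @return n x n integer matrix; rows are orderings of 1..n.
#' @export
balanced_latin_square <- function(n) {
  if (n %% 2 != 0) stop("balanced construction requires even order")
  first <- numeric(n)
  first[seq(1, n, by = 2)] <- 1 + (seq(1, n, by = 2) - 1) / 2
  first[seq(2, n, by = 2)] <- n + 1 - seq(2, n, by = 2) / 2
  t(vapply(seq_len(n), function(i) ((first - 1 + (i - 1)) %% n) + 1,
           numeric(n)))
}

#' Build the full trial schedule of the experiment
#'
#' Per participant: 64 practice trials (eight per condition, two practice
#' actors, conditions in the fixed order AV, V, A, AdV, dAV, dV, dA, dAdV),
#' then 6 experimental blocks x 8 condition sub-blocks x 16 trials = 768
#' main trials.  Every (emotion, actor, condition) triple occurs exactly
#' once in the main trials: each condition's 96 stimuli (12 emotions x 8
#' actors) are split over the six blocks, 16 per block, in seeded random
#' order.  The sub-block condition order within each block follows a
#' balanced Latin square, rotated across blocks and participants.
#'
#' @param participants data frame with columns `participant` and
#'   `age_group` (`"young"`/`"older"`), or an integer number of
#'   participants (all `"young"`).
#' @param seed RNG seed; the schedule is a pure function of
#'   `(participants, seed)`.
#' @param split_actors if `TRUE` (the two-session variant used for older
#'   participants), each condition presents four of the eight actors in
#'   blocks 1-3 and the remaining four in blocks 4-6.
#' @return data frame of `trial_record` rows: `participant`, `age_group`,
#'   `practice`, `block` (0 for practice), `sub_block`, `trial`,
#'   `condition`, `emotion`, `actor`, `response` (NA), `correct` (NA).
#' @export
build_schedule <- function(participants, seed = 1, split_actors = FALSE) {
  if (is.numeric(participants) && length(participants) == 1L) {
    participants <- data.frame(participant = sprintf("p%02d",
                                                     seq_len(participants)),
                               age_group = "young")
  }
  if (nrow(participants) < 1) stop("need at least one participant")
  conds <- condition_set()$condition
  emos <- emotion_set()$emotion
  actors <- sprintf("a%d", 1:8)
  practice_actors <- c("p1", "p2")
  practice_order <- c("AV", "V", "A", "AdV", "dAV", "dV", "dA", "dAdV")
  lsq <- balanced_latin_square(8)
  withr::with_seed(seed, {
    res <- lapply(seq_len(nrow(participants)), function(p) {
      pid <- participants$participant[p]
      grp <- participants$age_group[p]
      # practice: 8 trials per condition from the 24 practice stimuli
      prac_stims <- expand.grid(emotion = emos, actor = practice_actors,
                                stringsAsFactors = FALSE)
      prac <- do.call(rbind, lapply(seq_along(practice_order), function(i) {
        pick <- prac_stims[sample(nrow(prac_stims), 8), ]
        data.frame(participant = pid, age_group = grp, practice = TRUE,
                   block = 0L, sub_block = i,
                   condition = practice_order[i],
                   emotion = pick$emotion, actor = pick$actor)
      }))
      # main: per condition, shuffle the 96 stimuli and deal 16 per block
      per_cond <- lapply(conds, function(cond) {
        stims <- expand.grid(emotion = emos, actor = actors,
                             stringsAsFactors = FALSE)
        if (split_actors) {
          half <- sample(actors, 4)
          s1 <- stims[stims$actor %in% half, ]
          s2 <- stims[!stims$actor %in% half, ]
          ord <- rbind(s1[sample(nrow(s1)), ], s2[sample(nrow(s2)), ])
        } else {
          ord <- stims[sample(nrow(stims)), ]
        }
        ord$slot <- rep(1:6, each = 16)
        ord
      })
      names(per_cond) <- conds
      main <- do.call(rbind, lapply(1:6, function(b) {
        row <- lsq[((p - 1) + (b - 1)) %% 8 + 1, ]
        do.call(rbind, lapply(seq_along(row), function(sb) {
          cond <- conds[row[sb]]
          sel <- per_cond[[cond]][per_cond[[cond]]$slot == b, ]
          data.frame(participant = pid, age_group = grp, practice = FALSE,
                     block = b, sub_block = sb, condition = cond,
                     emotion = sel$emotion, actor = sel$actor)
        }))
      }))
      out <- rbind(prac, main)
      out$trial <- seq_len(nrow(out))
      out
    })
  })
  sched <- do.call(rbind, res)
  sched$response <- NA_character_
  sched$correct <- NA
  rownames(sched) <- NULL
  sched
}
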