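# Shared fixtures, all generated in code.

# one-frame landmark table with simple round numbers, for exact AOI checks
simple_trackpoint_frame <- function() {
  pts <- data.frame(
    landmark = aoi_landmarks(),
    x = c(1060, 990, 1025,   # left eyebrow outer/inner/middle (actor left = +x)
          860, 930, 895,     # right eyebrow
          1010, 910,         # pupils
          960,               # nose tip
          985, 935,          # nostrils
          960, 960, 1010, 910,  # mouth top/bottom/left/right
          1300, 620),        # hands
    y = c(330, 320, 310,
          330, 320, 310,
          370, 370,
          450,
          460, 460,
          500, 560, 530, 530,
          800, 800))
  pts$frame <- 1L
  pts$t_ms <- 0
  pts
}

# gaze event table builder
gaze_events <- function(kind, t_on, t_off, x = NA_real_, y = NA_real_,
                        amplitude = NA_real_, trial = 1) {
  data.frame(trial = trial, kind = kind, t_on = t_on, t_off = t_off,
             x = x, y = y, amplitude = amplitude)
}

# confusion table with chosen marginal counts for one emotion
confusion_fixture <- function(correct, occurrence, responded,
                              emotion = "Joy", other = "Fear") {
  emos <- emotion_set()$emotion
  tab <- matrix(0L, 12, 12, dimnames = list(emos, emos))
  tab[emotion, emotion] <- correct
  tab[emotion, other] <- occurrence - correct
  tab[other, emotion] <- responded - correct
  structure(tab, class = c("confusion_table", "matrix"))
}
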