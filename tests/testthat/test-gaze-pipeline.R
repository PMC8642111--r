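test_that("windowing keeps, truncates, and drops events correctly", {
  g <- gaze_events("fixation", t_on = c(100, 900, 1200),
                   t_off = c(400, 1200, 1500), x = 1, y = 1)
  w <- window_trial(g, stim_on = 0, window_ms = 1000)
  expect_equal(nrow(w), 2)
  expect_equal(w$t_off - w$t_on, c(300, 100))  # straddler truncated to 100
  # a window fully containing the events changes nothing
  w2 <- window_trial(g, stim_on = 0, window_ms = 2000)
  expect_equal(w2$t_off - w2$t_on, g$t_off - g$t_on)
  # truncation never increases a duration
  set.seed(13)
  for (i in 1:20) {
    on <- runif(8, -200, 1200); off <- on + runif(8, 1, 600)
    gg <- gaze_events("fixation", on, off, x = 0, y = 0)
    ww <- window_trial(gg, 0, 1000)
    orig <- (gg$t_off - gg$t_on)[gg$t_off > 0 & gg$t_on < 1000]
    expect_true(all(ww$t_off - ww$t_on <= orig + 1e-9))
  }
  # onset-relative re-expression
  w3 <- window_trial(gaze_events("fixation", 1100, 1400, 1, 1), stim_on = 1000)
  expect_equal(c(w3$t_on, w3$t_off), c(100, 400))
})

test_that("blink exclusion uses a strict single-blink threshold", {
  long <- rbind(gaze_events("fixation", 0, 500, 1, 1, trial = 1),
                gaze_events("blink", 500, 801, trial = 1))      # 301 ms
  at <- rbind(gaze_events("fixation", 0, 500, 1, 1, trial = 2),
              gaze_events("blink", 500, 800, trial = 2))        # exactly 300
  two <- rbind(gaze_events("blink", 0, 200, trial = 3),
               gaze_events("blink", 400, 600, trial = 3))       # 2 x 200 ms
  g <- rbind(long, at, two)
  out <- exclude_blink_trials(g)
  expect_equal(attr(out, "excluded_trials"), 1)
  expect_setequal(unique(out$trial), c(2, 3))
})

test_that("the saccade filter removes only over-threshold amplitudes", {
  g <- rbind(gaze_events("saccade", 0, 30, amplitude = 50),
             gaze_events("saccade", 40, 70, amplitude = 49.6),
             gaze_events("fixation", 80, 300, 1, 1))
  out <- filter_saccades(g)
  expect_equal(nrow(out), 2)                     # 49.6 itself is kept
  expect_false(any(out$amplitude > 49.6, na.rm = TRUE))
  # on a generated fixture, the planted over-threshold fraction is removed
  set.seed(5)
  amps <- c(runif(490, 0.5, 40), runif(10, 50, 80))
  gg <- gaze_events("saccade", seq_along(amps) * 10,
                    seq_along(amps) * 10 + 5, amplitude = amps)
  expect_equal(nrow(filter_saccades(gg)), 490)
  expect_error(filter_saccades(gg, -1), "positive")
})

test_that("correct-response filtering matches trials and honors the flag", {
  g <- gaze_events("fixation", 0, 100, 1, 1, trial = rep(1:10, each = 2))
  resp <- data.frame(trial = 1:10, correct = rep(c(TRUE, FALSE), c(3, 7)))
  expect_equal(unique(keep_correct_trials(g, resp)$trial), 1:3)
  expect_equal(nrow(keep_correct_trials(g, resp, only_correct = FALSE)), 20)
  all_ok <- data.frame(trial = 1:10, correct = TRUE)
  expect_identical(keep_correct_trials(g, all_ok), g)
  none <- data.frame(trial = 1:10, correct = FALSE)
  expect_equal(nrow(keep_correct_trials(g, none)), 0)
  expect_error(keep_correct_trials(g, resp[1:5, ]), "unmatched")
})

test_that("AOI rectangles follow the printed corner rules", {
  tp <- simple_trackpoint_frame()
  a <- build_aoi_track(tp)
  r <- a$rects
  eyes <- r[r$aoi == "eyes", ]
  nose <- r[r$aoi == "nose", ]
  mouth <- r[r$aoi == "mouth", ]
  # eye-nose border: midpoint of left-pupil y (370) and nose-tip y (450)
  expect_equal(eyes$bottom, 410)
  expect_equal(nose$top, eyes$bottom)            # shared border, no gap
  # nose-mouth border: midpoint of right-nostril y (460) and mouth-top y (500)
  expect_equal(nose$bottom, 480)
  expect_equal(mouth$top, nose$bottom)
  # merged eyes span both eyebrow boxes plus 10 px, unexpanded at the border
  expect_equal(eyes$left, 860 - 10)
  expect_equal(eyes$right, 1060 + 10)
  expect_equal(eyes$top, 310 - 10)
  # mouth is 100 px wide from its corners, expanded to 120
  expect_equal(mouth$right - mouth$left, 120)
  expect_equal(mouth$bottom, 560 + 10)
  # nose sides from the nostrils plus expansion
  expect_equal(nose$left, 935 - 10)
  expect_equal(nose$right, 985 + 10)
  # hands are fixed-size boxes around the track point (plus expansion)
  hands <- r[r$aoi == "hands", ]
  expect_equal(hands$right - hands$left, rep(100, 2))
  expect_error(build_aoi_track(tp[tp$landmark != "nose_tip", ]),
               "nose_tip")
})

test_that("AOIs never overlap, including hands trimmed against the face", {
  # hands placed to collide with the mouth box
  tp <- simple_trackpoint_frame()
  tp$x[tp$landmark == "hand_left"] <- 1040
  tp$y[tp$landmark == "hand_left"] <- 560
  a <- build_aoi_track(tp)
  r <- a$rects
  for (i in seq_len(nrow(r) - 1)) for (j in (i + 1):nrow(r)) {
    ox <- min(r$right[i], r$right[j]) - max(r$left[i], r$left[j])
    oy <- min(r$bottom[i], r$bottom[j]) - max(r$top[i], r$top[j])
    expect_false(ox > 1e-9 && oy > 1e-9)
  }
  # and across many generated frames
  tr <- gen_actor_trackpoints(12, seed = 4)
  rr <- build_aoi_track(tr)$rects
  for (fr in unique(rr$frame)) {
    r <- rr[rr$frame == fr, ]
    for (i in seq_len(nrow(r) - 1)) for (j in (i + 1):nrow(r)) {
      ox <- min(r$right[i], r$right[j]) - max(r$left[i], r$left[j])
      oy <- min(r$bottom[i], r$bottom[j]) - max(r$top[i], r$top[j])
      expect_false(ox > 1e-9 && oy > 1e-9)
    }
  }
})

test_that("fixation proportions partition to one over AOIs plus elsewhere", {
  a <- build_aoi_track(simple_trackpoint_frame())
  mouth_mid <- c(960, 520)
  g <- rbind(
    gaze_events("fixation", 0, 400, mouth_mid[1], mouth_mid[2], trial = 1),
    gaze_events("fixation", 450, 700, 100, 100, trial = 2),   # elsewhere
    gaze_events("fixation", 0, 500, mouth_mid[1], mouth_mid[2], trial = 3),
    gaze_events("fixation", 500, 1000, 100, 100, trial = 3))
  p <- fixation_proportions(g, a)
  p1 <- p[p$trial == 1, ]
  expect_equal(p1$proportion[p1$aoi == "mouth"], 1)
  expect_equal(p1$proportion[p1$aoi == "eyes"], 0)
  expect_equal(p[p$trial == 2 & p$aoi == "elsewhere", "proportion"], 1)
  p3 <- p[p$trial == 3, ]
  expect_equal(p3$proportion[p3$aoi == "mouth"], 0.5)
  expect_equal(p3$proportion[p3$aoi == "elsewhere"], 0.5)
  for (tr in unique(p$trial))
    expect_equal(sum(p$proportion[p$trial == tr]), 1)
})

test_that("points just inside the expansion margin count as on the AOI", {
  a <- build_aoi_track(simple_trackpoint_frame())
  mouth <- a$rects[a$rects$aoi == "mouth", ]
  inside <- c(mouth$left + 5, mouth$bottom - 5)   # 5 px inside the corner
  outside <- c(mouth$left - 5, mouth$bottom + 5)
  g <- rbind(gaze_events("fixation", 0, 100, inside[1], inside[2], trial = 1),
             gaze_events("fixation", 0, 100, outside[1], outside[2],
                         trial = 2))
  p <- fixation_proportions(g, a)
  expect_equal(p[p$trial == 1 & p$aoi == "mouth", "proportion"], 1)
  expect_equal(p[p$trial == 2 & p$aoi == "mouth", "proportion"], 0)
})

test_that("trials without fixation samples are flagged and excluded", {
  a <- build_aoi_track(simple_trackpoint_frame())
  g <- rbind(gaze_events("saccade", 0, 50, amplitude = 3, trial = 1),
             gaze_events("fixation", 0, 200, 960, 520, trial = 2))
  p <- fixation_proportions(g, a)
  expect_equal(attr(p, "no_fixation_trials"), "1")
  expect_setequal(unique(p$trial), 2)
})
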