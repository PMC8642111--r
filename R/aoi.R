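#' Landmark names required to build the face and hand AOIs
#'
#' Left/right are in reference to the actor (the actor's left is generally
#' on the right of the screen).
#'
#' @return character vector of landmark names.
#' @export
aoi_landmarks <- function() {
  c("eyebrow_outer_left", "eyebrow_inner_left", "eyebrow_middle_left",
    "eyebrow_outer_right", "eyebrow_inner_right", "eyebrow_middle_right",
    "pupil_left", "pupil_right", "nose_tip",
    "nostril_left", "nostril_right",
    "mouth_top", "mouth_bottom", "mouth_left", "mouth_right",
    "hand_left", "hand_right")
}

#' Build dynamic AOI rectangles from per-frame track points
#'
#' Constructs the eyes, nose, mouth, and hands areas of interest for every
#' frame from tracked landmarks, following fixed corner rules:
#' \itemize{
#'   \item eye boxes: lateral/medial x from the outer/inner eyebrow points,
#'     top from the middle eyebrow point, bottom at the eye-nose border
#'     (midpoint of the left-pupil and nose-tip y positions); the left and
#'     right eye boxes are merged into a single eyes region.
#'   \item nose: from the eye-nose border down to the nose-mouth border
#'     (midpoint of the right-nostril and mouth-top y positions), lateral
#'     x from the two nostrils.
#'   \item mouth: lateral x from the mouth corners, top at the nose-mouth
#'     border, bottom at the mouth-bottom point.
#'   \item hands: a fixed-size box centered on each hand track point
#'     (single-point tracking gives no extent, so the box size is a
#'     parameter).
#' }
#' Every AOI is then expanded by 10 pixels on each side, except across the
#' shared eye-nose and nose-mouth borders, which stay in place so the face
#' AOIs tile without gap or overlap.  Hand boxes are trimmed wherever they
#' would overlap a face AOI.
#'
#' @param tp track points in long format: data frame with `frame`, `t_ms`,
#'   `landmark`, `x`, `y` (see [aoi_landmarks()] for required names).
#' @param expand_px expansion margin in pixels (default 10).
#' @param hand_box_px side length of the square hand AOI (default 80).
#' @return an `aoi_track`: list with `rects` (data frame `frame`, `t_ms`,
#'   `aoi`, `part`, `left`, `top`, `right`, `bottom`) and `frames`.
#' @export
build_aoi_track <- function(tp, expand_px = 10, hand_box_px = 80) {
  need <- aoi_landmarks()
  frames <- sort(unique(tp$frame))
  rects <- do.call(rbind, lapply(frames, function(fr) {
    pts <- tp[tp$frame == fr, ]
    miss <- setdiff(need, pts$landmark)
    if (length(miss) > 0)
      stop("frame ", fr, ": missing landmark(s) ",
           paste(miss, collapse = ", "))
    P <- function(lm, ax) pts[[ax]][match(lm, pts$landmark)]
    border_en <- (P("pupil_left", "y") + P("nose_tip", "y")) / 2
    border_nm <- (P("nostril_right", "y") + P("mouth_top", "y")) / 2
    eye <- function(side) {
      xs <- c(P(paste0("eyebrow_outer_", side), "x"),
              P(paste0("eyebrow_inner_", side), "x"))
      c(left = min(xs), top = P(paste0("eyebrow_middle_", side), "y"),
        right = max(xs), bottom = border_en)
    }
    el <- eye("left"); er <- eye("right")
    eyes <- c(left = min(el["left"], er["left"]) - expand_px,
              top = min(el["top"], er["top"]) - expand_px,
              right = max(el["right"], er["right"]) + expand_px,
              bottom = border_en)                      # shared border: no expansion
    nose <- c(left = min(P("nostril_left", "x"), P("nostril_right", "x")) -
                expand_px,
              top = border_en, right = max(P("nostril_left", "x"),
                                           P("nostril_right", "x")) + expand_px,
              bottom = border_nm)
    mouth <- c(left = min(P("mouth_left", "x"), P("mouth_right", "x")) -
                 expand_px,
               top = border_nm,
               right = max(P("mouth_left", "x"), P("mouth_right", "x")) +
                 expand_px,
               bottom = P("mouth_bottom", "y") + expand_px)
    face <- rbind(eyes = eyes, nose = nose, mouth = mouth)
    h <- hand_box_px / 2 + expand_px
    hands <- do.call(rbind, lapply(c("left", "right"), function(side) {
      r <- c(left = P(paste0("hand_", side), "x") - h,
             top = P(paste0("hand_", side), "y") - h,
             right = P(paste0("hand_", side), "x") + h,
             bottom = P(paste0("hand_", side), "y") + h)
      for (i in seq_len(nrow(face))) r <- trim_rect(r, face[i, ])
      r
    }))
    df <- as.data.frame(rbind(face, hands))
    df$aoi <- c("eyes", "nose", "mouth", "hands", "hands")
    df$part <- c("eyes", "nose", "mouth", "hand_left", "hand_right")
    df$frame <- fr
    df$t_ms <- pts$t_ms[1]
    df[, c("frame", "t_ms", "aoi", "part", "left", "top", "right", "bottom")]
  }))
  rects <- rects[rects$right > rects$left & rects$bottom > rects$top, ]
  rownames(rects) <- NULL
  structure(list(rects = rects,
                 frames = unique(rects[, c("frame", "t_ms")])),
            class = "aoi_track")
}

# shrink rectangle r so its interior no longer intersects rectangle face;
# removes the least area, dropping r entirely if it is swallowed
trim_rect <- function(r, face) {
  ix <- c(max(r["left"], face["left"]), min(r["right"], face["right"]))
  iy <- c(max(r["top"], face["top"]), min(r["bottom"], face["bottom"]))
  if (ix[1] >= ix[2] || iy[1] >= iy[2]) return(r)  # no interior overlap
  cands <- list(
    replace(r, "left", face["right"]), replace(r, "right", face["left"]),
    replace(r, "top", face["bottom"]), replace(r, "bottom", face["top"]))
  areas <- vapply(cands, function(c2)
    max(0, c2["right"] - c2["left"]) * max(0, c2["bottom"] - c2["top"]),
    numeric(1))
  out <- cands[[which.max(areas)]]
  if (areas[which.max(areas)] <= 0) out["right"] <- out["left"]  # degenerate
  out
}

#' Per-trial fixation proportions on dynamic AOIs
#'
#' Resamples every fixation of a windowed, filtered gaze table into 1-ms
#' time-points at the fixation's position, tests each time-point against
#' the AOI rectangles of the temporally nearest frame, and returns the
#' proportion of time-points on each AOI plus the `elsewhere` remainder.
#' The proportions partition to 1 within each trial.  Trials without any
#' fixation time-point are excluded and listed in the `"no_fixation_trials"`
#' attribute.
#'
#' A time-point lies on an AOI when `left <= x <= right` and
#' `top <= y < bottom` (half-open vertically, so shared borders belong to
#' the lower AOI and nothing is counted twice).
#'
#' @param g gaze event table with `trial`, `kind`, `t_on`, `t_off`, `x`, `y`.
#' @param a an [build_aoi_track()] object.
#' @param step_ms resampling step (default 1 ms, the native tracker rate).
#' @return long data frame `trial`, `aoi`, `proportion`.
#' @export
fixation_proportions <- function(g, a, step_ms = 1) {
  stopifnot(inherits(a, "aoi_track"))
  aois <- c("eyes", "nose", "mouth", "hands", "elsewhere")
  trials <- unique(g$trial)
  no_fix <- character(0)
  out <- list()
  for (tr in trials) {
    fx <- g[g$trial == tr & g$kind == "fixation", , drop = FALSE]
    pts <- fixation_timepoints(fx, step_ms)
    if (nrow(pts) == 0) { no_fix <- c(no_fix, as.character(tr)); next }
    fr_idx <- vapply(pts$t, function(t)
      which.min(abs(a$frames$t_ms - t)), integer(1))
    fr <- a$frames$frame[fr_idx]
    lab <- vapply(seq_len(nrow(pts)), function(i) {
      rc <- a$rects[a$rects$frame == fr[i], , drop = FALSE]
      hit <- rc$left <= pts$x[i] & pts$x[i] <= rc$right &
        rc$top <= pts$y[i] & pts$y[i] < rc$bottom
      if (any(hit)) rc$aoi[which(hit)[1]] else "elsewhere"
    }, character(1))
    prop <- vapply(aois, function(z) mean(lab == z), numeric(1))
    out[[length(out) + 1]] <- data.frame(trial = tr, aoi = aois,
                                         proportion = as.numeric(prop))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(trial = character(0), aoi = character(0),
               proportion = numeric(0))
  rownames(res) <- NULL
  attr(res, "no_fixation_trials") <- no_fix
  res
}

# 1-ms grid of fixation time-points: one sample per whole step of duration,
# at the fixation's mean position
fixation_timepoints <- function(fx, step_ms = 1) {
  if (nrow(fx) == 0)
    return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0)))
  do.call(rbind, lapply(seq_len(nrow(fx)), function(i) {
    n <- floor((fx$t_off[i] - fx$t_on[i]) / step_ms)
    if (n <= 0)
      return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0)))
    data.frame(t = fx$t_on[i] + (seq_len(n) - 0.5) * step_ms,
               x = fx$x[i], y = fx$y[i])
  }))
}
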