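#' Confusion table of responses for one analysis cell
#'
#' Tabulates true emotion against response over a set of trials (typically
#' one participant x condition cell of the design).  Rows are presented
#' emotions, columns responses; row sums recover the occurrence counts of
#' each emotion in the cell.
#'
#' @param trials data frame with columns `emotion` and `response` (NA
#'   responses are dropped).
#' @param levels emotion labels fixing the table dimensions (default the
#'   12-emotion set).
#' @return 12 x 12 integer matrix of class `confusion_table`.
#' @export
confusion_table <- function(trials, levels = emotion_set()$emotion) {
  trials <- trials[!is.na(trials$response), , drop = FALSE]
  tab <- table(factor(trials$emotion, levels = levels),
               factor(trials$response, levels = levels))
  structure(unclass(tab), class = c("confusion_table", "matrix"))
}

#' Unbiased hit-rate
#'
#' Bias-corrected recognition accuracy for one category: the squared number
#' of correct responses divided by the product of the category's occurrences
#' and the number of times the category was used as a response,
#' `Hu = correct^2 / (occurrences x responded)`.  Equivalently Hu is
#' recall x precision, so it never exceeds the raw hit-rate and penalizes a
#' bias toward over-using a response.  When the response was never used
#' (so `correct` is necessarily 0) Hu is 0, the limit of the formula.
#'
#' @param tab a [confusion_table()].
#' @param emotion category label (row/column name); if missing, Hu is
#'   returned for every category.
#' @return Hu in \[0, 1\], named when vectorized.
#' @export
unbiased_hit_rate <- function(tab, emotion = NULL) {
  stopifnot(inherits(tab, "confusion_table"))
  if (is.null(emotion)) {
    out <- vapply(rownames(tab), function(e) unbiased_hit_rate(tab, e),
                  numeric(1))
    return(out)
  }
  if (!emotion %in% rownames(tab)) stop("unknown emotion: ", emotion)
  correct <- tab[emotion, emotion]
  occurrence <- sum(tab[emotion, ])
  responded <- sum(tab[, emotion])
  if (occurrence == 0)
    stop("Hu undefined: '", emotion, "' never occurred in this cell")
  if (responded == 0) return(0)
  correct^2 / (occurrence * responded)
}

#' Arcsine transform of a proportion
#'
#' `asin(sqrt(p))`, the variance-stabilizing transform applied to unbiased
#' hit-rates and fixation proportions before linear modelling.  Monotone,
#' mapping \[0, 1\] to \[0, pi/2\].
#'
#' @param p proportion(s) in \[0, 1\].
#' @return transformed value(s) in radians.
#' @export
arcsine_transform <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Chance-level proportion of a forced choice
#'
#' @param n_emotions number of response alternatives (>= 2).
#' @return 1 / n_emotions.
#' @export
chance_level <- function(n_emotions) {
  if (n_emotions < 2) stop("need at least two response alternatives")
  1 / n_emotions
}

#' Unbiased hit-rates for every participant x condition cell
#'
#' Convenience wrapper producing the analysis table for the accuracy
#' models: one row per participant x condition x emotion with the raw and
#' unbiased hit-rate and the arcsine-transformed Hu.  Practice trials are
#' excluded.
#'
#' @param trials completed trial records (see [build_schedule()] and
#'   [gen_responses()]).
#' @return data frame with `participant`, `age_group`, `condition`,
#'   `emotion`, `hit_rate`, `hu`, `hu_asin`.
#' @export
hu_table <- function(trials) {
  trials <- trials[!trials$practice & !is.na(trials$response), ]
  cells <- unique(trials[, c("participant", "age_group", "condition")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- trials$participant == cells$participant[i] &
      trials$condition == cells$condition[i]
    tab <- confusion_table(trials[sel, ])
    hu <- unbiased_hit_rate(tab)
    raw <- diag(tab) / rowSums(tab)
    data.frame(participant = cells$participant[i],
               age_group = cells$age_group[i],
               condition = cells$condition[i],
               emotion = names(hu), hit_rate = as.numeric(raw),
               hu = as.numeric(hu), hu_asin = arcsine_transform(hu))
  }))
  rownames(out) <- NULL
  out
}
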