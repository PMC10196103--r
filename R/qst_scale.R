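# Nine-item clinical scale for rapid Q/S/T diagnosis: binarize imaging
# features at fixed cutoffs, sum per-type points (0-16 each) and take the
# argmax with tie priority T > S > Q. Plus the generic single-threshold
# max-AUC cutoff finder used to calibrate such items.

#' Point table of the clinical scale
#'
#' Per-type points awarded by each of the nine scale items. Each type's
#' points sum to 16, the maximum attainable score.
#'
#' @return Named list `Q`, `S`, `T` of named integer vectors.
#' @export
scale_points <- function() {
  list(
    Q = c(pituitary_not_seen = 8L, ap_lt_cutoff = 3L, si_gt_cutoff = 2L,
          anterior = 3L),
    S = c(no_dilatation = 5L, anterior = 2L, widest_inferior = 2L,
          anterior_volume_gt = 3L, aspect_gt = 4L),
    T = c(pituitary_seen = 6L, dilatation = 3L, posterior = 1L,
          widest_superior = 2L, fossa_lt = 4L)
  )
}

#' Default thresholds of the clinical scale
#'
#' The printed cutoffs for the measured quantities (AP diameter < 3.5 cm,
#' SI diameter > 3.5 cm, fossa volume < 2.1 cm3, anterior volume > 0.8 cm3,
#' aspect ratio > 1.1; all strict as printed) plus operational defaults for
#' the qualitative items: a pituitary is "clearly seen" from 0.1 cm3 (an
#' order of magnitude above the near-invisible Q-type glands and well below
#' visible ones), ventricles are "dilated" from a ventricle/brain volume
#' ratio of 0.02, and the anterior/posterior position item uses a +-0.05
#' dead zone on the brain-normalized AP offset so a centred tumour scores
#' neither.
#'
#' @return Named list of thresholds, overridable item by item.
#' @export
scale_thresholds <- function() {
  list(pituitary_seen_cm3 = 0.1,
       ap_cutoff_cm = 3.5,
       si_cutoff_cm = 3.5,
       dilatation_ratio = 0.02,
       position_dead_zone = 0.05,
       widest_cutoff = 0.5,
       fossa_cutoff_cm3 = 2.1,
       anterior_volume_cutoff_cm3 = 0.8,
       aspect_cutoff = 1.1)
}

#' Binarize clinical features into the nine scale items
#'
#' Applies the scale thresholds to a [extract_features()] vector. Strict
#' inequalities follow the printed cutoffs, so boundary values score
#' nothing. A missing pituitary volume means the gland was not seen; other
#' missing features leave their item `NA` (scored as 0 by [score_items()]).
#'
#' @param features A `clinical_features` vector.
#' @param thresholds Threshold list, default [scale_thresholds()]; partial
#'   lists are completed with the defaults.
#' @return List of class `scale_items` with the nine items:
#'   `pituitary_clearly_seen`, `tumor_ap_lt_cutoff`, `tumor_si_gt_cutoff`,
#'   `ventricle_dilated` (logicals), `tumor_position`
#'   (`"anterior"/"posterior"/"neutral"`), `widest_location`
#'   (`"inferior"/"superior"`), `fossa_volume_lt_cutoff`,
#'   `anterior_volume_gt_cutoff`, `aspect_gt_cutoff` (logicals).
#' @export
binarize_items <- function(features, thresholds = scale_thresholds()) {
  stopifnot(inherits(features, "clinical_features"))
  th <- modifyList(scale_thresholds(), thresholds)
  f <- unclass(features)
  pit_vol <- f[["pituitary_volume_cm3"]]
  brain_vol <- f[["brain_volume_cm3"]]
  vent_vol <- f[["ventricle_volume_cm3"]]
  ap_off <- f[["tumor_vs_brain_ap"]]
  position <- if (is.na(ap_off)) NA_character_
    else if (ap_off >= th$position_dead_zone) "anterior"
    else if (ap_off <= -th$position_dead_zone) "posterior"
    else "neutral"
  widest <- f[["widest_level_fraction"]]
  structure(list(
    pituitary_clearly_seen =
      !is.na(pit_vol) && pit_vol >= th$pituitary_seen_cm3,
    tumor_ap_lt_cutoff = f[["tumor_extent_ap_cm"]] < th$ap_cutoff_cm,
    tumor_si_gt_cutoff = f[["tumor_extent_si_cm"]] > th$si_cutoff_cm,
    ventricle_dilated = if (is.na(brain_vol) || brain_vol <= 0) NA
      else (vent_vol / brain_vol) >= th$dilatation_ratio,
    tumor_position = position,
    widest_location = if (is.na(widest)) NA_character_
      else if (widest < th$widest_cutoff) "inferior" else "superior",
    fossa_volume_lt_cutoff = f[["tumor_fossa_volume_cm3"]] <
      th$fossa_cutoff_cm3,
    anterior_volume_gt_cutoff = f[["tumor_anterior_volume_cm3"]] >
      th$anterior_volume_cutoff_cm3,
    aspect_gt_cutoff = f[["aspect_ratio_ap_si"]] > th$aspect_cutoff
  ), class = "scale_items")
}

#' Score the nine scale items
#'
#' Sums the per-type points of every item that fires. A neutral position
#' contributes to no type; a missing (`NA`) item contributes 0 everywhere.
#' Scores range from 0 to 16 per type.
#'
#' @param items A [binarize_items()] result (or a plain list with the same
#'   element names).
#' @return Integer vector `c(Q=, S=, T=)`, class `scale_scores`.
#' @export
score_items <- function(items) {
  p <- scale_points()
  tt <- function(x) isTRUE(x)                 # NA-safe
  q <- tt(!items$pituitary_clearly_seen) * p$Q[["pituitary_not_seen"]] +
       tt(items$tumor_ap_lt_cutoff) * p$Q[["ap_lt_cutoff"]] +
       tt(items$tumor_si_gt_cutoff) * p$Q[["si_gt_cutoff"]] +
       tt(identical(items$tumor_position, "anterior")) * p$Q[["anterior"]]
  s <- tt(!items$ventricle_dilated) * p$S[["no_dilatation"]] +
       tt(identical(items$tumor_position, "anterior")) * p$S[["anterior"]] +
       tt(identical(items$widest_location, "inferior")) *
         p$S[["widest_inferior"]] +
       tt(items$anterior_volume_gt_cutoff) * p$S[["anterior_volume_gt"]] +
       tt(items$aspect_gt_cutoff) * p$S[["aspect_gt"]]
  t <- tt(items$pituitary_clearly_seen) * p$T[["pituitary_seen"]] +
       tt(items$ventricle_dilated) * p$T[["dilatation"]] +
       tt(identical(items$tumor_position, "posterior")) * p$T[["posterior"]] +
       tt(identical(items$widest_location, "superior")) *
         p$T[["widest_superior"]] +
       tt(items$fossa_volume_lt_cutoff) * p$T[["fossa_lt"]]
  structure(c(Q = as.integer(q), S = as.integer(s), T = as.integer(t)),
            class = "scale_scores")
}

#' @export
print.scale_scores <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Diagnose the subtype from scale scores
#'
#' The type with the maximum score is diagnosed; equal scores resolve by
#' the priority T > S > Q (T-type carries the gravest surgical
#' implications).
#'
#' @param scores A [score_items()] result or named numeric `c(Q=,S=,T=)`.
#' @return `"Q"`, `"S"` or `"T"`.
#' @export
classify_scores <- function(scores) {
  s <- c(Q = scores[["Q"]], S = scores[["S"]], T = scores[["T"]])
  pri <- c(T = 3L, S = 2L, Q = 1L)[names(s)]
  names(s)[order(-s, -pri)][1]
}

#' Scale diagnosis straight from a label map or feature vector
#'
#' Convenience wrapper chaining [extract_features()], [binarize_items()],
#' [score_items()] and [classify_scores()].
#'
#' @param x A [label_map()] or `clinical_features` vector.
#' @param thresholds Passed to [binarize_items()].
#' @return List with `items`, `scores` and `type`.
#' @export
qst_scale <- function(x, thresholds = scale_thresholds()) {
  feats <- if (inherits(x, "clinical_features")) x else extract_features(x)
  items <- binarize_items(feats, thresholds)
  scores <- score_items(items)
  list(items = items, scores = scores, type = classify_scores(scores))
}

#' Maximum-AUC threshold for one feature
#'
#' Scans all midpoints between consecutive sorted distinct values and both
#' directions (feature above vs below threshold predicts the outcome) and
#' returns the threshold maximizing the AUC of the resulting binary
#' predictor, i.e. (sensitivity + specificity) / 2. Ties resolve to the
#' lowest threshold (and `>=` direction first).
#'
#' @param values Numeric feature values.
#' @param outcome Logical outcome, same length, both classes present with
#'   at least 2 samples each.
#' @return List with `threshold`, `direction` (`">="` or `"<"`, the side
#'   predicting `TRUE`), `auc` and `youden`.
#' @export
find_cutoff <- function(values, outcome) {
  stopifnot(length(values) == length(outcome))
  outcome <- as.logical(outcome)
  if (sum(outcome) < 2 || sum(!outcome) < 2)
    stop("need at least 2 samples in each outcome class", call. = FALSE)
  v <- sort(unique(values))
  if (length(v) < 2) stop("values are constant", call. = FALSE)
  mids <- (v[-1] + v[-length(v)]) / 2
  best <- list(auc = -Inf)
  npos <- sum(outcome); nneg <- sum(!outcome)
  for (t in mids) {
    for (dir in c(">=", "<")) {
      pred <- if (dir == ">=") values >= t else values < t
      sens <- sum(pred & outcome) / npos
      spec <- sum(!pred & !outcome) / nneg
      auc <- (sens + spec) / 2
      if (auc > best$auc + 1e-12)
        best <- list(threshold = t, direction = dir, auc = auc,
                     youden = sens + spec - 1)
    }
  }
  best
}
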