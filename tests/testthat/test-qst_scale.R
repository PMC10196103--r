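test_that("binarization honours the printed strict cutoffs", {
  it <- binarize_items(make_features(pituitary_volume_cm3 = 0.01))
  expect_false(it$pituitary_clearly_seen)
  it2 <- binarize_items(make_features(pituitary_volume_cm3 = 0.45))
  expect_true(it2$pituitary_clearly_seen)

  expect_true(binarize_items(
    make_features(tumor_extent_ap_cm = 3.0))$tumor_ap_lt_cutoff)
  expect_false(binarize_items(
    make_features(tumor_extent_ap_cm = 3.5))$tumor_ap_lt_cutoff)
  expect_false(binarize_items(
    make_features(tumor_extent_si_cm = 3.5))$tumor_si_gt_cutoff)

  # boundary values score nothing: strict inequalities as printed
  expect_false(binarize_items(
    make_features(aspect_ratio_ap_si = 1.1))$aspect_gt_cutoff)
  expect_true(binarize_items(
    make_features(aspect_ratio_ap_si = 1.1000001))$aspect_gt_cutoff)
  expect_false(binarize_items(
    make_features(tumor_fossa_volume_cm3 = 2.1))$fossa_volume_lt_cutoff)
  expect_false(binarize_items(
    make_features(tumor_anterior_volume_cm3 = 0.8))$anterior_volume_gt_cutoff)

  # position dead zone
  expect_equal(binarize_items(
    make_features(tumor_vs_brain_ap = 0.02))$tumor_position, "neutral")
  expect_equal(binarize_items(
    make_features(tumor_vs_brain_ap = 0.2))$tumor_position, "anterior")
  expect_equal(binarize_items(
    make_features(tumor_vs_brain_ap = -0.2))$tumor_position, "posterior")

  # ventricle dilation is a volume ratio
  expect_true(binarize_items(make_features(ventricle_volume_cm3 = 8,
                                           brain_volume_cm3 = 280)
                             )$ventricle_dilated)
  expect_false(binarize_items(make_features(ventricle_volume_cm3 = 3,
                                            brain_volume_cm3 = 280)
                              )$ventricle_dilated)

  # a missing pituitary volume means the gland was not seen
  f <- make_features(); f["pituitary_volume_cm3"] <- NA
  attr(f, "missing") <- is.na(unclass(f))
  expect_false(binarize_items(f)$pituitary_clearly_seen)

  # thresholds are configurable
  it3 <- binarize_items(make_features(aspect_ratio_ap_si = 1.05),
                        thresholds = list(aspect_cutoff = 1.0))
  expect_true(it3$aspect_gt_cutoff)
})

test_that("item scoring reproduces hand-summed point totals", {
  all_q <- list(pituitary_clearly_seen = FALSE, tumor_ap_lt_cutoff = TRUE,
                tumor_si_gt_cutoff = TRUE, ventricle_dilated = FALSE,
                tumor_position = "anterior", widest_location = "inferior",
                fossa_volume_lt_cutoff = FALSE,
                anterior_volume_gt_cutoff = TRUE, aspect_gt_cutoff = FALSE)
  s1 <- score_items(all_q)
  expect_identical(unclass(s1)[c("Q", "S", "T")], c(Q = 16L, S = 12L, T = 0L))

  all_t <- list(pituitary_clearly_seen = TRUE, tumor_ap_lt_cutoff = FALSE,
                tumor_si_gt_cutoff = TRUE, ventricle_dilated = TRUE,
                tumor_position = "posterior", widest_location = "superior",
                fossa_volume_lt_cutoff = TRUE,
                anterior_volume_gt_cutoff = FALSE, aspect_gt_cutoff = FALSE)
  s2 <- score_items(all_t)
  expect_identical(unclass(s2)[c("Q", "S", "T")], c(Q = 2L, S = 0L, T = 16L))

  missing_all <- list(pituitary_clearly_seen = NA, tumor_ap_lt_cutoff = NA,
                      tumor_si_gt_cutoff = NA, ventricle_dilated = NA,
                      tumor_position = NA_character_,
                      widest_location = NA_character_,
                      fossa_volume_lt_cutoff = NA,
                      anterior_volume_gt_cutoff = NA, aspect_gt_cutoff = NA)
  expect_identical(unclass(score_items(missing_all))[c("Q", "S", "T")],
                   c(Q = 0L, S = 0L, T = 0L))
})

test_that("diagnosis takes the argmax with tie priority T > S > Q", {
  expect_equal(classify_scores(c(Q = 16, S = 12, T = 0)), "Q")
  expect_equal(classify_scores(c(Q = 10, S = 10, T = 10)), "T")
  expect_equal(classify_scores(c(Q = 0, S = 7, T = 7)), "T")
  expect_equal(classify_scores(c(Q = 9, S = 9, T = 3)), "S")
  expect_equal(classify_scores(c(Q = 5, S = 4, T = 3)), "Q")
})

test_that("exhaustive item enumeration bounds scores at 16 per type", {
  bools <- c(TRUE, FALSE)
  grid <- expand.grid(pit = bools, ap = bools, si = bools, dil = bools,
                      pos = c("anterior", "posterior", "neutral"),
                      wid = c("inferior", "superior", "neutral"),
                      fossa = bools, antv = bools, asp = bools,
                      stringsAsFactors = FALSE)
  scores <- t(apply(grid, 1, function(r) {
    score_items(list(
      pituitary_clearly_seen = as.logical(r[["pit"]]),
      tumor_ap_lt_cutoff = as.logical(r[["ap"]]),
      tumor_si_gt_cutoff = as.logical(r[["si"]]),
      ventricle_dilated = as.logical(r[["dil"]]),
      tumor_position = r[["pos"]], widest_location = r[["wid"]],
      fossa_volume_lt_cutoff = as.logical(r[["fossa"]]),
      anterior_volume_gt_cutoff = as.logical(r[["antv"]]),
      aspect_gt_cutoff = as.logical(r[["asp"]])))
  }))
  expect_equal(unname(apply(scores, 2, max)), c(16, 16, 16))
  expect_equal(unname(apply(scores, 2, min)), c(0, 0, 0))
  # the per-type point tables themselves sum to 16
  expect_equal(unname(vapply(scale_points(), sum, numeric(1))),
               c(16, 16, 16))
})

test_that("turning a Q item on never lowers the Q score", {
  base <- list(pituitary_clearly_seen = TRUE, tumor_ap_lt_cutoff = FALSE,
               tumor_si_gt_cutoff = FALSE, ventricle_dilated = TRUE,
               tumor_position = "neutral", widest_location = "superior",
               fossa_volume_lt_cutoff = FALSE,
               anterior_volume_gt_cutoff = FALSE, aspect_gt_cutoff = FALSE)
  s0 <- score_items(base)
  for (flip in list(list(pituitary_clearly_seen = FALSE),
                    list(tumor_ap_lt_cutoff = TRUE),
                    list(tumor_si_gt_cutoff = TRUE),
                    list(tumor_position = "anterior"))) {
    s1 <- score_items(modifyList(base, flip))
    expect_gte(s1[["Q"]], s0[["Q"]])
  }
})

test_that("scale diagnosis chains from a label map deterministically", {
  ph <- cached_phantom("S")
  r1 <- qst_scale(ph$map)
  r2 <- qst_scale(ph$map)
  expect_identical(r1, r2)
  expect_equal(r1$type, "S")
})

test_that("max-AUC cutoff search matches an exhaustive oracle", {
  # perfectly separated values
  r <- find_cutoff(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE))
  expect_gt(r$threshold, 2); expect_lt(r$threshold, 8)
  expect_equal(r$auc, 1)
  expect_equal(r$direction, ">=")

  # anti-separated data flips the direction
  r2 <- find_cutoff(c(1, 2, 8, 9), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 1)
  expect_equal(r2$direction, "<")

  # random data vs a brute-force scan over all midpoints and directions
  set.seed(31)
  for (rep in 1:5) {
    v <- round(rnorm(50), 2)
    y <- runif(50) < 0.4
    if (sum(y) < 2 || sum(!y) < 2) next
    got <- find_cutoff(v, y)
    sv <- sort(unique(v))
    best <- -Inf
    for (t in (sv[-1] + sv[-length(sv)]) / 2) for (dir in c(TRUE, FALSE)) {
      pred <- if (dir) v >= t else v < t
      auc <- (sum(pred & y) / sum(y) + sum(!pred & !y) / sum(!y)) / 2
      if (auc > best) best <- auc
    }
    expect_equal(got$auc, best)
  }

  expect_error(find_cutoff(1:5, rep(TRUE, 5)), "outcome class")
  expect_error(find_cutoff(rep(1, 6), rep(c(TRUE, FALSE), 3)), "constant")
})
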