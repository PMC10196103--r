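test_that("tissue volume is voxel count times voxel volume", {
  v <- array(0L, c(10, 10, 10))
  v[1:10, 1:10, 1:10][seq_len(1000)] <- 4L
  m <- label_map(v)                       # spacing (6, 0.45, 0.45)
  expect_equal(tissue_volume(m, 4), 1000 * 6 * 0.45 * 0.45 / 1000)  # 1.215
  expect_equal(tissue_volume(m, 1), 0)
  expect_error(tissue_volume(m, 0), "1..6")
})

test_that("extents are inclusive bounding boxes in cm", {
  v <- array(0L, c(12, 30, 40))
  v[3, 5, 7] <- 1L
  m <- label_map(v)
  expect_equal(tissue_extents(m, 1), c(LR = 0.6, AP = 0.045, SI = 0.045))

  v2 <- array(0L, c(12, 30, 40))
  v2[2:11, 3:22, 5:34] <- 6L              # 10 x 20 x 30 box
  m2 <- label_map(v2)
  expect_equal(tissue_extents(m2, 6),
               c(LR = 10 * 0.6, AP = 20 * 0.045, SI = 30 * 0.045))
  expect_equal(tissue_extents(m2, 2), c(LR = 0, AP = 0, SI = 0))
})

test_that("tuberculum landmark picks superior, then anterior, then low-x", {
  v <- array(0L, c(6, 10, 10))
  v[2:5, 3:6, 2:4] <- 3L
  v[1, 1, 10] <- 1L                       # tumor somewhere else
  lm <- locate_tuberculum(label_map(v))
  expect_equal(lm$k_ts, 4)                # most superior sinus level
  expect_equal(lm$j_ts, 6)                # most anterior at that level
  expect_equal(lm$index, c(2, 6, 4))      # lowest sagittal index

  # two equally superior voxels at different AP -> more anterior wins
  v2 <- array(0L, c(4, 8, 8))
  v2[2, 3, 5] <- 3L
  v2[2, 6, 5] <- 3L
  lm2 <- locate_tuberculum(label_map(v2))
  expect_equal(lm2$j_ts, 6)

  expect_error(locate_tuberculum(label_map(array(0L, c(2, 2, 2)))), "sinus")
})

test_that("fossa and anterior volumes partition the tumour", {
  ph <- cached_phantom("Q")
  lm <- locate_tuberculum(ph$map)
  total <- tissue_volume(ph$map, 1)
  fossa <- tumor_fossa_volume(ph$map, lm)
  above <- sum(ph$map$voxels[, , lm$k_ts:dim(ph$map)[3]] == 1L) *
    prod(ph$map$spacing) / 1000
  expect_equal(fossa + above, total)

  ant <- tumor_anterior_volume(ph$map, lm)
  post <- sum(ph$map$voxels[, seq_len(lm$j_ts), ] == 1L) *
    prod(ph$map$spacing) / 1000
  expect_equal(ant + post, total)

  # tumour strictly above the plane contributes nothing to the fossa
  v <- array(0L, c(4, 8, 8))
  v[2, 4, 2] <- 3L
  v[2, 3, 5:7] <- 1L
  m <- label_map(v)
  expect_equal(tumor_fossa_volume(m, locate_tuberculum(m)), 0)
})

test_that("anterior volume uses a strict anterior half-space", {
  v <- array(0L, c(4, 8, 8))
  v[2, 4, 2] <- 3L                         # landmark at j = 4
  v[2, 2:4, 5] <- 1L                       # tumour at/posterior of the plane
  m <- label_map(v)
  expect_equal(tumor_anterior_volume(m, locate_tuberculum(m)), 0)
  v[2, 5, 5] <- 1L                         # one voxel strictly anterior
  m2 <- label_map(v)
  expect_equal(tumor_anterior_volume(m2, locate_tuberculum(m2)),
               prod(m2$spacing) / 1000)
})

test_that("relative position is centred, signed and translation-invariant", {
  v <- array(0L, c(8, 21, 21))
  v[3:6, 6:16, 6:16] <- 4L                 # brain block
  v[4:5, 10:12, 10:12] <- 1L               # tumour at the brain centre
  m <- label_map(v)
  expect_equal(unname(relative_position(m, "brain")), c(0, 0, 0),
               tolerance = 1e-9)

  # translating tumour and brain together changes nothing
  v2 <- array(0L, c(8, 21, 21))
  v2[3:6, 8:18, 4:14] <- 4L
  v2[4:5, 12:14, 8:10] <- 1L
  expect_equal(relative_position(label_map(v2), "brain"),
               relative_position(m, "brain"), tolerance = 1e-9)

  # the T archetype sits posterior to the brain
  t_pos <- relative_position(cached_phantom("T")$map, "brain")
  expect_lt(t_pos[["AP"]], -0.05)
  # missing brain flags the sentinel
  v3 <- array(0L, c(4, 6, 6)); v3[2, 3, 3] <- 1L
  p3 <- relative_position(label_map(v3), "brain")
  expect_true(all(is.na(p3)))
  expect_true(attr(p3, "missing"))
})

test_that("widest-level fraction encodes pyramid orientation", {
  # downward-widening wedge (widest at the bottom)
  v <- array(0L, c(4, 20, 10))
  for (k in 2:8) v[2, 8 + seq_len(max(1, 10 - k)), k] <- 1L
  expect_lt(widest_level_fraction(label_map(v)), 0.5)

  # upward-widening wedge
  v2 <- array(0L, c(4, 20, 10))
  for (k in 2:8) v2[2, 8 + seq_len(max(1, k - 1)), k] <- 1L
  expect_gt(widest_level_fraction(label_map(v2)), 0.5)

  # uniform box: every level equally wide, ties resolve to the lowest level
  v3 <- array(0L, c(4, 20, 10))
  v3[2, 5:10, 3:7] <- 1L
  expect_equal(widest_level_fraction(label_map(v3)), 0)

  # single-level tumour is neutral
  v4 <- array(0L, c(4, 20, 10))
  v4[2, 5:10, 4] <- 1L
  expect_equal(widest_level_fraction(label_map(v4)), 0.5)
})

test_that("aspect ratio divides AP by SI extent", {
  v <- array(0L, c(8, 40, 40))
  v[2:4, 3:22, 5:24] <- 1L                # AP 20 voxels, SI 20 voxels
  expect_equal(aspect_ratio(label_map(v)), 1)
  v2 <- array(0L, c(8, 120, 100))
  v2[2:4, 3 + 0:92, 5 + 0:66] <- 1L       # 93 x 67 voxels -> 4.185/3.015 cm
  expect_equal(aspect_ratio(label_map(v2)), (93 * 0.045) / (67 * 0.045))
})

test_that("the feature vector has 34 entries and is deterministic", {
  ph <- cached_phantom("S")
  f1 <- extract_features(ph$map)
  f2 <- extract_features(ph$map)
  expect_length(f1, 34)
  expect_identical(names(f1), clinical_feature_names())
  expect_identical(unclass(f1), unclass(f2))
  expect_false(any(attr(f1, "missing")))
})

test_that("all 34 features are invariant to a left-right mirror", {
  for (ty in c("Q", "T")) {
    ph <- cached_phantom(ty)
    flipped <- label_map(ph$map$voxels[rev(seq_len(dim(ph$map)[1])), , ],
                         ph$map$spacing)
    expect_equal(unclass(extract_features(flipped)),
                 unclass(extract_features(ph$map)), tolerance = 1e-9)
  }
})

test_that("archetype features fall on the correct side of every cutoff", {
  fq <- extract_features(cached_phantom("Q")$map)
  fs <- extract_features(cached_phantom("S")$map)
  ft <- extract_features(cached_phantom("T")$map)
  th <- scale_thresholds()

  expect_lt(fq[["pituitary_volume_cm3"]], th$pituitary_seen_cm3)
  expect_lt(fq[["tumor_extent_ap_cm"]], th$ap_cutoff_cm)
  expect_gt(fq[["tumor_extent_si_cm"]], th$si_cutoff_cm)
  expect_gt(fq[["tumor_vs_brain_ap"]], th$position_dead_zone)
  expect_gt(fq[["tumor_fossa_volume_cm3"]], th$fossa_cutoff_cm3)

  expect_gt(fs[["pituitary_volume_cm3"]], th$pituitary_seen_cm3)
  expect_gt(fs[["aspect_ratio_ap_si"]], th$aspect_cutoff)
  expect_gt(fs[["tumor_anterior_volume_cm3"]],
            th$anterior_volume_cutoff_cm3)
  expect_lt(fs[["widest_level_fraction"]], th$widest_cutoff)
  expect_lt(fs[["ventricle_volume_cm3"]] / fs[["brain_volume_cm3"]],
            th$dilatation_ratio)

  expect_gt(ft[["pituitary_volume_cm3"]], th$pituitary_seen_cm3)
  expect_gte(ft[["ventricle_volume_cm3"]] / ft[["brain_volume_cm3"]],
             th$dilatation_ratio)
  expect_lt(ft[["tumor_vs_brain_ap"]], -th$position_dead_zone)
  expect_gte(ft[["widest_level_fraction"]], th$widest_cutoff)
  expect_lt(ft[["tumor_fossa_volume_cm3"]], th$fossa_cutoff_cm3)
})

test_that("a missing landmark flags the dependent features only", {
  v <- array(0L, c(6, 16, 16))
  v[2:5, 3:14, 3:14] <- 4L
  v[3:4, 6:10, 6:10] <- 1L
  f <- extract_features(label_map(v))     # no sphenoid sinus anywhere
  miss <- attr(f, "missing")
  expect_true(all(miss[c("tumor_vs_sellar_lr", "tumor_vs_sellar_ap",
                         "tumor_vs_sellar_si", "tumor_fossa_volume_cm3",
                         "tumor_anterior_volume_cm3")]))
  expect_false(miss[["tumor_volume_cm3"]])
  expect_false(miss[["aspect_ratio_ap_si"]])
})
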