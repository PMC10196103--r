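test_that("archetype specs sit on the correct side of every scale cutoff", {
  q <- archetype_spec("Q"); s <- archetype_spec("S"); t <- archetype_spec("T")
  expect_lte(q$pituitary_volume_cm3, 0.02)
  expect_lt(q$tumor_ap_cm, 3.5)
  expect_gt(q$tumor_si_cm, 3.5)
  expect_gt(s$tumor_ap_cm / s$tumor_si_cm, 1.1)
  expect_equal(s$ventricle_dilation_factor, 1)
  expect_lt(s$widest_level_fraction, 0.5)
  expect_gt(t$ventricle_dilation_factor, 1)
  expect_gt(t$widest_level_fraction, 0.5)
  expect_gte(t$pituitary_volume_cm3, 0.1)
})

test_that("phantom generation is deterministic given the spec", {
  a <- generate_phantom(archetype_spec("T", seed = 5))
  b <- generate_phantom(archetype_spec("T", seed = 5))
  expect_identical(a$map$voxels, b$map$voxels)
  expect_identical(a$mri$voxels, b$mri$voxels)
})

test_that("generated morphology matches the generating parameters", {
  for (ty in c("Q", "S", "T")) {
    sp <- archetype_spec(ty)
    ph <- cached_phantom(ty)
    ext <- tissue_extents(ph$map, 1)
    # in-plane extents within one in-plane voxel + partial-volume slack
    expect_lt(abs(ext[["AP"]] * 10 - sp$tumor_ap_cm * 10), 1.5,
              label = paste(ty, "AP extent error (mm)"))
    expect_lt(abs(ext[["SI"]] * 10 - sp$tumor_si_cm * 10), 1.5,
              label = paste(ty, "SI extent error (mm)"))
    # sagittal extent within one slice thickness + the inclusive voxel
    expect_lt(abs(ext[["LR"]] * 10 - sp$tumor_lr_cm * 10), 12.5,
              label = paste(ty, "LR extent error (mm)"))
    # requested volumes within 15%
    pit <- tissue_volume(ph$map, 2)
    expect_lt(abs(pit - sp$pituitary_volume_cm3),
              0.15 * sp$pituitary_volume_cm3 + 0.002,
              label = paste(ty, "pituitary volume"))
    vent <- tissue_volume(ph$map, 6)
    vreq <- 3.3 * sp$ventricle_dilation_factor
    expect_lt(abs(vent - vreq) / vreq, 0.15,
              label = paste(ty, "ventricle volume"))
    # all classes present except possibly the cistern
    present <- sort(unique(as.vector(ph$map$voxels)))
    expect_true(all(c(0L, 1L, 2L, 3L, 4L, 6L) %in% present))
  }
})

test_that("Q phantoms are taller than deep; intrasellar fraction respected", {
  q <- cached_phantom("Q")
  ext <- tissue_extents(q$map, 1)
  expect_gt(ext[["SI"]], ext[["AP"]])

  sp0 <- archetype_spec("S"); sp0$intrasellar_fraction <- 0
  ph0 <- generate_phantom(sp0)
  lm <- locate_tuberculum(ph0$map)
  expect_equal(tumor_fossa_volume(ph0$map, lm), 0)

  # requested fractions are recovered from the voxelized tumour
  spf <- archetype_spec("Q")
  phf <- generate_phantom(spf)
  lmf <- locate_tuberculum(phf$map)
  frac <- tumor_fossa_volume(phf$map, lmf) / tissue_volume(phf$map, 1)
  expect_lt(abs(frac - spf$intrasellar_fraction), 0.03)
})

test_that("cohorts respect the mixture, jitter bounds and the seed", {
  co <- generate_cohort(10, mixture = c(1, 0, 0), seed = 3)
  expect_true(all(co$manifest$type == "Q"))
  expect_equal(nrow(co$manifest), 10)

  co1 <- generate_cohort(4, seed = 77)
  co2 <- generate_cohort(4, seed = 77)
  expect_identical(co1$manifest, co2$manifest)
  expect_identical(co1$samples[[2]]$map$voxels, co2$samples[[2]]$map$voxels)

  expect_error(generate_cohort(5, mixture = c(0.5, 0.5, 0.5)), "sum")
})

test_that("133-sample type draws stay within binomial 99% bounds of 29/22/82", {
  mix <- c(0.218, 0.165, 0.617)
  target <- c(Q = 29, S = 22, T = 82)
  set.seed(9)
  types <- sellarqst:::draw_cohort_types(133, mix)
  counts <- table(factor(types, levels = qst_types()))
  for (i in 1:3) {
    bounds <- qbinom(c(0.005, 0.995), 133, mix[i])
    expect_gte(counts[[i]], bounds[1])
    expect_lte(counts[[i]], bounds[2])
    # the bounds themselves bracket the reference cohort's counts
    expect_gte(target[[i]], bounds[1])
    expect_lte(target[[i]], bounds[2])
  }
})

test_that("impossible geometry raises a geometry error", {
  sp <- archetype_spec("S")
  sp$shape <- c(4L, 24L, 24L)
  expect_error(generate_phantom(sp), "grid too small")
})

test_that("cohorts round-trip through NIfTI with a manifest", {
  co <- generate_cohort(2, seed = 21)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2)
  back <- read_volume(file.path(dir, "sample001_labels.nii.gz"),
                      expect_labels = TRUE)
  expect_identical(back$voxels, co$samples[[1]]$map$voxels)
})
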