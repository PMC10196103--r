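# Synthetic sellar phantom: ellipsoidal tissues placed around a sphenoid
# sinus block whose superior-anterior corner acts as the tuberculum sellae
# surrogate. Tumour morphology (extents, widest-level profile, intrasellar
# and anterior volume fractions) is controlled per Q/S/T archetype.

# Fixed anatomy of the default phantom, in mm. The grid is
# 24 x 192 x 192 voxels at (6, 0.45, 0.45) mm spacing: 144 x 86.4 x 86.4 mm.
phantom_layout <- function() {
  list(
    sinus_x_half = 33, sinus_y = c(48, 66), sinus_z = c(6, 24),
    brain_center = c(72, 38, 52), brain_semi = c(66, 36, 30),
    vent_centers = list(c(60, 30, 66), c(84, 30, 66)),
    vent_cand_semi = c(11, 13, 10),
    vent_base_cm3 = 3.3,                   # both sides, before dilation
    pit_cand_center = c(72, 54, 26), pit_cand_semi = c(16, 14, 9),
    cist_center = c(72, 54, 31), cist_semi = c(24, 13, 4.5),
    intensity = c(background = 0.05, tumor = 0.95, pituitary = 0.85,
                  sphenoid_sinus = 0.10, brain = 0.55,
                  suprasellar_cistern = 0.30, ventricle = 0.20)
  )
}

#' Phantom generation parameters
#'
#' Bundles everything that controls a synthetic sellar phantom: grid and
#' spacing, the Q/S/T archetype, the pituitary volume, the tumour's
#' anteroposterior (AP), supero-inferior (SI) and left-right (LR) extents,
#' its centre offset from the tuberculum surrogate, the lateral-ventricle
#' dilation factor, where along SI the tumour is widest, and what fractions
#' of the tumour lie below the tuberculum plane (intrasellar) and anterior
#' to it.
#'
#' @param archetype One of `"Q"`, `"S"`, `"T"`.
#' @param shape Integer grid dimensions (LR, PA, IS).
#' @param spacing Voxel spacing in mm; default matches a 3T sagittal
#'   acquisition with 6 mm slices and 0.45 mm in-plane pixels.
#' @param pituitary_volume_cm3 Requested pituitary volume.
#' @param tumor_ap_cm,tumor_si_cm,tumor_lr_cm Tumour extents in cm.
#' @param tumor_center_offset mm offset of the tumour centre from the
#'   tuberculum surrogate, per axis.
#' @param ventricle_dilation_factor Volume multiplier for the lateral
#'   ventricles (>= 1; > 1 models hydrocephalus).
#' @param widest_level_fraction Relative SI position of the tumour's widest
#'   AP cross-section, 0 = inferior ("positive pyramid") to 1 = superior
#'   ("inverted pyramid").
#' @param intrasellar_fraction Fraction of tumour volume inferior to the
#'   tuberculum plane.
#' @param anterior_fraction Fraction of tumour volume anterior to the
#'   tuberculum plane.
#' @param noise_sd Gaussian intensity noise standard deviation.
#' @param seed Integer seed controlling the intensity noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(archetype = "S",
                         shape = c(24L, 192L, 192L),
                         spacing = c(6, 0.45, 0.45),
                         pituitary_volume_cm3 = 0.45,
                         tumor_ap_cm = 3.5, tumor_si_cm = 3.5,
                         tumor_lr_cm = 3.0,
                         tumor_center_offset = c(0, -12, 14),
                         ventricle_dilation_factor = 1,
                         widest_level_fraction = 0.5,
                         intrasellar_fraction = 0.1,
                         anterior_fraction = 0.1,
                         noise_sd = 0.05,
                         seed = 1L) {
  archetype <- match.arg(archetype, qst_types())
  stopifnot(length(shape) == 3L, all(shape >= 2),
            tumor_ap_cm > 0, tumor_si_cm > 0, tumor_lr_cm > 0,
            pituitary_volume_cm3 >= 0, ventricle_dilation_factor >= 1,
            widest_level_fraction >= 0, widest_level_fraction <= 1,
            intrasellar_fraction >= 0, intrasellar_fraction <= 1,
            anterior_fraction >= 0, anterior_fraction <= 1,
            noise_sd >= 0)
  spacing <- validate_spacing(spacing)
  structure(list(
    archetype = archetype, shape = as.integer(shape), spacing = spacing,
    pituitary_volume_cm3 = pituitary_volume_cm3,
    tumor_ap_cm = tumor_ap_cm, tumor_si_cm = tumor_si_cm,
    tumor_lr_cm = tumor_lr_cm,
    tumor_center_offset = as.numeric(tumor_center_offset),
    ventricle_dilation_factor = ventricle_dilation_factor,
    widest_level_fraction = widest_level_fraction,
    intrasellar_fraction = intrasellar_fraction,
    anterior_fraction = anterior_fraction,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Archetypal phantom parameters for each QST subtype
#'
#' Returns a [phantom_spec()] encoding the morphological archetype of the
#' requested subtype: Q has a near-invisible pituitary, smaller AP than SI
#' diameter, an anterior position and a large intrasellar volume; S has a
#' visible pituitary, AP/SI aspect ratio 1.4, a large volume anterior to the
#' tuberculum, its widest level inferior and no ventricular dilation; T has
#' a visible pituitary, dilated ventricles, a posterior position, its widest
#' level superior and a small intrasellar volume.
#'
#' @param type `"Q"`, `"S"` or `"T"`.
#' @param seed Seed stored in the spec (controls intensity noise).
#' @return A `phantom_spec`.
#' @export
archetype_spec <- function(type, seed = 1L) {
  type <- match.arg(type, qst_types())
  switch(type,
    Q = phantom_spec("Q", pituitary_volume_cm3 = 0.01,
                     tumor_ap_cm = 3.0, tumor_si_cm = 4.2, tumor_lr_cm = 3.0,
                     tumor_center_offset = c(0, -14, 14),
                     ventricle_dilation_factor = 1,
                     widest_level_fraction = 0.5,
                     intrasellar_fraction = 0.35, anterior_fraction = 0.05,
                     seed = seed),
    S = phantom_spec("S", pituitary_volume_cm3 = 0.49,
                     tumor_ap_cm = 4.2, tumor_si_cm = 3.0, tumor_lr_cm = 3.0,
                     tumor_center_offset = c(0, -8, 14),
                     ventricle_dilation_factor = 1,
                     widest_level_fraction = 0.25,
                     intrasellar_fraction = 0.03, anterior_fraction = 0.20,
                     seed = seed),
    T = phantom_spec("T", pituitary_volume_cm3 = 0.45,
                     tumor_ap_cm = 3.0, tumor_si_cm = 3.6, tumor_lr_cm = 3.2,
                     tumor_center_offset = c(0, -38, 16),
                     ventricle_dilation_factor = 2.5,
                     widest_level_fraction = 0.75,
                     intrasellar_fraction = 0.04, anterior_fraction = 0,
                     seed = seed)
  )
}

# mm coordinates of voxel centres along each axis
grid_mm <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - 0.5) * spacing[a])
}

# quadratic form ((p - c)/s)^2 summed over axes, as a full 3D array
ellipsoid_field <- function(mm, center, semi) {
  tx <- ((mm[[1]] - center[1]) / semi[1])^2
  ty <- ((mm[[2]] - center[2]) / semi[2])^2
  tz <- ((mm[[3]] - center[3]) / semi[3])^2
  f <- outer(ty, tz, "+")                       # PA x IS
  aperm(outer(f, tx, "+"), c(3L, 1L, 2L))       # LR x PA x IS
}

# mask of the k voxels with smallest field value among `allowed`;
# approximates an ellipsoidal tissue of a requested volume that moulds
# itself around higher-priority structures (tumour compression)
quantile_mask <- function(field, volume_cm3, voxel_mm3, allowed = NULL) {
  k <- round(volume_cm3 * 1000 / voxel_mm3)
  msk <- array(FALSE, dim = dim(field))
  if (k < 1) return(msk)
  v <- as.vector(field)
  ok <- if (is.null(allowed)) TRUE else as.vector(allowed)
  # expand the candidate shell until it holds k voxels, then sort only it
  thr <- 1
  repeat {
    idx <- which(ok & v <= thr)
    if (length(idx) >= k || thr > 64) break
    thr <- thr * 2
  }
  k <- min(k, length(idx))
  sel <- idx[order(v[idx])[seq_len(k)]]
  msk[sel] <- TRUE
  msk
}

# Tumour mask: per-SI-level ellipse in (LR, PA) whose AP half-width follows
# a triangular profile peaking at `widest` of the SI span (pinched to 25%
# at the ends), voxelized on the grid.
tumor_mask_base <- function(mm, center, ap, si, lr, widest) {
  zc <- mm[[3]]
  z0 <- center[3] - si / 2
  z1 <- center[3] + si / 2
  zpk <- z0 + widest * (si - 1e-9)
  w <- ifelse(zc < zpk,
              (zc - z0) / max(zpk - z0, 1e-9),
              (z1 - zc) / max(z1 - zpk, 1e-9))
  w[zc < z0 | zc > z1] <- NA
  a <- (ap / 2) * (0.25 + 0.75 * pmin(pmax(w, 0), 1))   # AP half-width
  tx <- ((mm[[1]] - center[1]) / (lr / 2))^2            # LR term
  yy <- (mm[[2]] - center[2])^2
  inv_a2 <- ifelse(is.na(a) | a <= 0, NA, 1 / a^2)
  f <- outer(yy, inv_a2)                                 # PA x IS
  m <- aperm(outer(f, tx, "+"), c(3L, 1L, 2L)) <= 1
  m[is.na(m)] <- FALSE
  m
}

# rigid shift of a logical mask along axis 2 or 3 (pads with FALSE)
shift_mask <- function(m, axis, s) {
  if (s == 0) return(m)
  d <- dim(m)
  out <- array(FALSE, dim = d)
  n <- d[axis]
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- src + s
  if (axis == 2L) out[, dst, ] <- m[, src, ]
  else out[, , dst] <- m[, , src]
  out
}

# shift `m` along `axis` so that the voxel fraction beyond `plane_idx`
# (direction "above": index > plane; "below": index < plane) is closest to
# `target`; exact for targets 0 and 1
solve_fraction_shift <- function(m, axis, plane_idx, target, direction) {
  counts <- apply(m, axis, sum)
  n <- sum(counts)
  if (n == 0) return(m)
  occ <- which(counts > 0)
  d <- dim(m)[axis]
  shifts <- (1 - min(occ)):(d - max(occ))
  frac <- vapply(shifts, function(s) {
    pos <- occ + s
    if (direction == "below") sum(counts[occ][pos < plane_idx]) / n
    else sum(counts[occ][pos > plane_idx]) / n
  }, numeric(1))
  if (target <= 0) {
    cand <- shifts[frac == 0]
    s <- if (length(cand)) cand[which.min(abs(cand))] else
      shifts[which.min(frac)]
  } else if (target >= 1) {
    cand <- shifts[frac == 1]
    s <- if (length(cand)) cand[which.min(abs(cand))] else
      shifts[which.max(frac)]
  } else {
    err <- abs(frac - target)
    best <- which(err == min(err))
    s <- shifts[best[which.min(abs(shifts[best]))]]
  }
  shift_mask(m, axis, s)
}

#' Generate a synthetic sellar phantom
#'
#' Builds a paired intensity volume and label map from a [phantom_spec()].
#' Tissues are voxelized ellipsoids placed around a sphenoid-sinus block;
#' overlaps resolve by priority tumour > pituitary > cistern > ventricle >
#' sinus > brain. The pituitary and ventricles mould around the tumour so
#' their requested volumes are met even under compression; the suprasellar
#' cistern may be partly or fully effaced by tumour. Intensities are fixed
#' per-class means plus i.i.d. Gaussian noise, seeded.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `mri` ([mri_volume()]), `map`
#'   ([label_map()]), `type` (the archetype) and `info` (tuberculum
#'   landmark index and achieved tissue volumes, cm3).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lay <- phantom_layout()
  shape <- spec$shape; spacing <- spec$spacing
  mm <- grid_mm(shape, spacing)
  voxmm3 <- prod(spacing)
  lab <- qst_labels()

  extent_mm <- shape * spacing
  if (any(c(spec$tumor_lr_cm, spec$tumor_ap_cm, spec$tumor_si_cm) * 10 >
          extent_mm))
    stop("grid too small for the requested tumor geometry", call. = FALSE)

  # sphenoid sinus block and tuberculum surrogate planes
  xc_grid <- extent_mm[1] / 2
  sinus <- outer(outer(abs(mm[[1]] - xc_grid) <= lay$sinus_x_half,
                       mm[[2]] >= lay$sinus_y[1] & mm[[2]] <= lay$sinus_y[2],
                       "&"),
                 mm[[3]] >= lay$sinus_z[1] & mm[[3]] <= lay$sinus_z[2], "&")
  if (!any(sinus)) stop("grid too small to place the sphenoid sinus",
                        call. = FALSE)
  k_ts <- max(which(apply(sinus, 3, any)))              # superior level
  j_ts <- max(which(apply(sinus[, , k_ts, drop = FALSE], 2, any)))
  lm_mm <- c(xc_grid, mm[[2]][j_ts], mm[[3]][k_ts])

  # tumour, then fraction-matching shifts along PA and IS
  tc <- lm_mm + spec$tumor_center_offset
  tum <- tumor_mask_base(mm, tc, spec$tumor_ap_cm * 10, spec$tumor_si_cm * 10,
                         spec$tumor_lr_cm * 10, spec$widest_level_fraction)
  if (!any(tum)) stop("grid too small to place the requested tumor",
                      call. = FALSE)
  tum <- solve_fraction_shift(tum, 2L, j_ts, spec$anterior_fraction, "above")
  tum <- solve_fraction_shift(tum, 3L, k_ts, spec$intrasellar_fraction,
                              "below")

  brain <- ellipsoid_field(mm, lay$brain_center, lay$brain_semi) <= 1
  cist <- ellipsoid_field(mm, lay$cist_center, lay$cist_semi) <= 1
  pit <- quantile_mask(ellipsoid_field(mm, lay$pit_cand_center,
                                       lay$pit_cand_semi),
                       spec$pituitary_volume_cm3, voxmm3, allowed = !tum)
  vtarget <- lay$vent_base_cm3 * spec$ventricle_dilation_factor / 2
  vent <- quantile_mask(ellipsoid_field(mm, lay$vent_centers[[1]],
                                        lay$vent_cand_semi),
                        vtarget, voxmm3, allowed = !tum) |
          quantile_mask(ellipsoid_field(mm, lay$vent_centers[[2]],
                                        lay$vent_cand_semi),
                        vtarget, voxmm3, allowed = !tum)

  vox <- array(0L, dim = shape)
  vox[brain] <- lab[["brain"]]
  vox[sinus] <- lab[["sphenoid_sinus"]]
  vox[vent] <- lab[["ventricle"]]
  vox[cist] <- lab[["suprasellar_cistern"]]
  vox[pit] <- lab[["pituitary"]]
  vox[tum] <- lab[["tumor"]]
  map <- label_map(vox, spacing)

  means <- lay$intensity[names(lab)]
  img <- array(means[vox + 1L], dim = shape)
  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed,
                           array(rnorm(prod(shape), 0, spec$noise_sd), shape))
  }
  vols <- tabulate(vox, nbins = 6L) * voxmm3 / 1000
  names(vols) <- names(lab)[-1]
  list(mri = mri_volume(img, spacing), map = map, type = spec$archetype,
       info = list(landmark = c(NA_integer_, j_ts, k_ts),
                   k_ts = k_ts, j_ts = j_ts, volumes_cm3 = vols))
}

#' Generate a cohort of jittered phantoms
#'
#' Draws each sample's subtype from `mixture`, jitters the archetype
#' parameters within bounds that keep every sample on its own side of the
#' clinical-scale cutoffs, and generates the phantoms. Reproducible given
#' `seed`.
#'
#' @param n Number of samples.
#' @param mixture Length-3 Q/S/T proportions summing to 1. The default
#'   mirrors the subtype prevalence of a 133-patient surgical series
#'   (21.8\% Q, 16.5\% S, 61.7\% T).
#' @param seed Integer seed.
#' @param shape,spacing Grid passed to every [phantom_spec()].
#' @return A list with class `phantom_cohort`: elements `samples` (list of
#'   [generate_phantom()] outputs plus each `spec`) and `manifest` (data
#'   frame of sample id, true type and spec parameters).
#' @export
generate_cohort <- function(n, mixture = c(0.218, 0.165, 0.617), seed = 1L,
                            shape = c(24L, 192L, 192L),
                            spacing = c(6, 0.45, 0.45)) {
  stopifnot(n >= 1)
  if (length(mixture) != 3L || any(mixture < 0) ||
      abs(sum(mixture) - 1) > 1e-6)
    stop("`mixture` must be 3 nonnegative proportions summing to 1",
         call. = FALSE)
  samples <- with_seed(seed, {
    types <- draw_cohort_types(n, mixture)
    lapply(seq_len(n), function(i) {
      sp <- jitter_spec(archetype_spec(types[i],
                                       seed = sample.int(.Machine$integer.max,
                                                         1)))
      sp$shape <- as.integer(shape); sp$spacing <- spacing
      ph <- generate_phantom(sp)
      ph$spec <- sp
      ph
    })
  })
  manifest <- do.call(rbind, lapply(seq_along(samples), function(i) {
    sp <- samples[[i]]$spec
    data.frame(id = i, type = sp$archetype,
               pituitary_volume_cm3 = sp$pituitary_volume_cm3,
               tumor_ap_cm = sp$tumor_ap_cm, tumor_si_cm = sp$tumor_si_cm,
               tumor_lr_cm = sp$tumor_lr_cm,
               ventricle_dilation_factor = sp$ventricle_dilation_factor,
               widest_level_fraction = sp$widest_level_fraction,
               intrasellar_fraction = sp$intrasellar_fraction,
               anterior_fraction = sp$anterior_fraction,
               seed = sp$seed)
  }))
  structure(list(samples = samples, manifest = manifest),
            class = "phantom_cohort")
}

# subtype draw for a cohort (uses the caller's RNG stream)
draw_cohort_types <- function(n, mixture) {
  sample(qst_types(), n, replace = TRUE, prob = mixture)
}

# bounded jitter keeping each parameter on its archetype's side of every
# scale cutoff (uses the RNG stream of the caller)
jitter_spec <- function(sp) {
  u <- function(lo, hi) runif(1, lo, hi)
  sp$tumor_ap_cm <- sp$tumor_ap_cm * u(0.93, 1.07)
  sp$tumor_si_cm <- sp$tumor_si_cm * u(0.93, 1.07)
  sp$tumor_lr_cm <- sp$tumor_lr_cm * u(0.9, 1.1)
  sp$pituitary_volume_cm3 <- sp$pituitary_volume_cm3 *
    if (sp$archetype == "Q") u(0.5, 1.6) else u(0.75, 1.25)
  if (sp$ventricle_dilation_factor > 1)
    sp$ventricle_dilation_factor <- sp$ventricle_dilation_factor * u(0.92, 1.1)
  sp$widest_level_fraction <-
    min(max(sp$widest_level_fraction + u(-0.1, 0.1), 0), 1)
  sp$intrasellar_fraction <-
    min(max(sp$intrasellar_fraction * u(0.7, 1.3), 0), 1)
  if (sp$anterior_fraction > 0)
    sp$anterior_fraction <- min(sp$anterior_fraction * u(0.75, 1.25), 1)
  sp$tumor_center_offset <- sp$tumor_center_offset +
    c(u(-2, 2), u(-2.5, 2.5), u(-2.5, 2.5))
  sp
}

#' Write a phantom cohort as NIfTI pairs plus a manifest
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$samples)) {
    s <- cohort$samples[[i]]
    write_volume(s$mri, file.path(dir, sprintf("sample%03d_mri.nii.gz", i)))
    write_volume(s$map, file.path(dir, sprintf("sample%03d_labels.nii.gz", i)))
  }
  mpath <- file.path(dir, "manifest.csv")
  write.csv(cohort$manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
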