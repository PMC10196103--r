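# The 34 clinical knowledge-based features measured on a sellar label map:
# per-tissue extents and volumes, tumour position relative to brain and to
# the tuberculum sellae surrogate, the widest-level fraction describing
# pyramid vs inverted-pyramid morphology, intrasellar and anterior tumour
# volumes, and the AP/SI aspect ratio.

#' Volume of one tissue class
#'
#' Voxel count times voxel volume, in cm3.
#'
#' @param map A [label_map()].
#' @param label Class index 1..6.
#' @return Volume in cm3 (0 for an absent tissue).
#' @export
tissue_volume <- function(map, label) {
  stopifnot(inherits(map, "label_map"))
  if (!label %in% 1:6)
    stop("`label` must be a foreground class 1..6", call. = FALSE)
  sum(map$voxels == label) * prod(map$spacing) / 1000
}

#' Axis-aligned extents of one tissue class
#'
#' Bounding-box side lengths of the class's voxels along the LR, AP and SI
#' axes, inclusive of the bounding voxels (a single voxel has the extent of
#' one voxel edge), in cm. Absent tissue yields zeros.
#'
#' @inheritParams tissue_volume
#' @return Named numeric `c(LR=, AP=, SI=)` in cm.
#' @export
tissue_extents <- function(map, label) {
  stopifnot(inherits(map, "label_map"))
  if (!label %in% 1:6)
    stop("`label` must be a foreground class 1..6", call. = FALSE)
  mask_extents_cm(map$voxels == label, map$spacing)
}

# occupancy counts of a logical 3D array along each axis, cheaply
axis_occupancy <- function(m) {
  s23 <- colSums(m)                      # dim2 x dim3 counts over axis1
  list(rowSums(m, dims = 1), rowSums(s23), colSums(s23))
}

mask_extents_cm <- function(m, spacing) {
  if (!any(m)) return(c(LR = 0, AP = 0, SI = 0))
  occ <- axis_occupancy(m)
  ext <- vapply(1:3, function(a) {
    w <- which(occ[[a]] > 0)
    (max(w) - min(w) + 1) * spacing[a]
  }, numeric(1))
  c(LR = ext[1], AP = ext[2], SI = ext[3]) / 10
}

#' Locate the tuberculum sellae surrogate
#'
#' The most superior sphenoid-sinus voxel, ties broken towards the most
#' anterior and then the lowest sagittal index. Its SI level `k_ts` defines
#' the horizontal plane separating the pituitary fossa (inferior) from the
#' suprasellar compartment, and its AP level `j_ts` the plane separating
#' "anterior to the tuberculum" from posterior.
#'
#' @param map A [label_map()] containing sphenoid sinus (label 3).
#' @return List of class `sellar_landmark`: `index` (voxel i, j, k),
#'   `k_ts`, `j_ts`, and `mm` (position in mm).
#' @export
locate_tuberculum <- function(map) {
  stopifnot(inherits(map, "label_map"))
  m <- map$voxels == 3L
  if (!any(m))
    stop("no sphenoid sinus voxels: landmark unavailable", call. = FALSE)
  k <- max(which(apply(m, 3, any)))
  sl <- m[, , k, drop = FALSE]
  j <- max(which(apply(sl, 2, any)))
  i <- min(which(sl[, j, 1]))
  structure(list(index = c(i, j, k), k_ts = k, j_ts = j,
                 mm = (c(i, j, k) - 0.5) * map$spacing),
            class = "sellar_landmark")
}

#' Tumour volume in the pituitary fossa
#'
#' Volume of tumour voxels strictly inferior to the tuberculum plane
#' (`k < k_ts`), in cm3. This is the intrasellar tumour burden: large for
#' infrasellar Q-type tumours, small (< 2.1 cm3 on the clinical scale) for
#' T-type tumours.
#'
#' @param map A [label_map()].
#' @param lm A [locate_tuberculum()] landmark.
#' @return Volume in cm3.
#' @export
tumor_fossa_volume <- function(map, lm) {
  stopifnot(inherits(map, "label_map"), inherits(lm, "sellar_landmark"))
  tum <- map$voxels == 1L
  if (lm$k_ts <= 1) return(0)
  sum(tum[, , seq_len(lm$k_ts - 1L)]) * prod(map$spacing) / 1000
}

#' Tumour volume anterior to the tuberculum sellae
#'
#' Volume of tumour voxels strictly anterior to the tuberculum plane
#' (`j > j_ts`), in cm3; voxels at the plane count as posterior. Large
#' anterior volumes (> 0.8 cm3 on the clinical scale) characterize S-type
#' tumours growing into the anterior cisterns.
#'
#' @inheritParams tumor_fossa_volume
#' @return Volume in cm3.
#' @export
tumor_anterior_volume <- function(map, lm) {
  stopifnot(inherits(map, "label_map"), inherits(lm, "sellar_landmark"))
  tum <- map$voxels == 1L
  d <- dim(tum)[2]
  if (lm$j_ts >= d) return(0)
  sum(tum[, (lm$j_ts + 1L):d, ]) * prod(map$spacing) / 1000
}

# centroid of a logical mask in voxel index coordinates
mask_centroid <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  colMeans(idx)
}

#' Tumour position relative to the brain or the sellar landmark
#'
#' For `reference = "brain"`: (tumour centroid - brain centroid) per axis in
#' mm, normalized by the brain's extent along that axis. For
#' `reference = "landmark"`: (tumour centroid - tuberculum position),
#' normalized by the tumour's own extent. Positive AP components mean the
#' tumour lies anterior to the reference; positive SI components superior.
#' The LR component is reported as an absolute lateral offset, since
#' sagittal handedness carries no diagnostic meaning.
#'
#' @param map A [label_map()] with tumour present.
#' @param reference `"brain"` or `"landmark"`.
#' @param lm Optional precomputed [locate_tuberculum()] landmark.
#' @return Named numeric `c(LR=, AP=, SI=)`, dimensionless; `NA`s with
#'   attribute `missing = TRUE` when the reference is absent.
#' @export
relative_position <- function(map, reference = c("brain", "landmark"),
                              lm = NULL) {
  stopifnot(inherits(map, "label_map"))
  reference <- match.arg(reference)
  tum <- map$voxels == 1L
  if (!any(tum)) stop("label map contains no tumor voxels", call. = FALSE)
  tc <- mask_centroid(tum) * map$spacing
  if (reference == "brain") {
    br <- map$voxels == 4L
    if (!any(br))
      return(structure(c(LR = NA_real_, AP = NA_real_, SI = NA_real_),
                       missing = TRUE))
    ref <- mask_centroid(br) * map$spacing
    norm <- tissue_extents(map, 4L) * 10
  } else {
    if (is.null(lm))
      lm <- tryCatch(locate_tuberculum(map), error = function(e) NULL)
    if (is.null(lm))
      return(structure(c(LR = NA_real_, AP = NA_real_, SI = NA_real_),
                       missing = TRUE))
    ref <- lm$mm
    norm <- tissue_extents(map, 1L) * 10
  }
  off <- (tc - ref) / pmax(norm, 1e-9)
  off[1] <- abs(off[1])
  c(LR = off[[1]], AP = off[[2]], SI = off[[3]])
}

#' Relative SI location of the tumour's widest AP cross-section
#'
#' For every SI level the tumour occupies, its transverse (AP) extent is
#' measured; the level of maximal extent `k*` (ties towards the lowest
#' level) is mapped to `(k* - k_min) / (k_max - k_min)` in \[0, 1\].
#' Values < 0.5 indicate a tumour widest inferiorly ("positive pyramid",
#' S-like); values >= 0.5 a tumour widest superiorly ("inverted pyramid",
#' T-like). A single-level tumour returns 0.5.
#'
#' @param map A [label_map()] with tumour present.
#' @return Fraction in \[0, 1\].
#' @export
widest_level_fraction <- function(map) {
  stopifnot(inherits(map, "label_map"))
  tum <- map$voxels == 1L
  if (!any(tum)) stop("label map contains no tumor voxels", call. = FALSE)
  occ_jk <- colSums(tum) > 0             # AP x SI occupancy
  levels <- which(colSums(occ_jk) > 0)
  if (length(levels) == 1L) return(0.5)
  ap <- vapply(levels, function(k) {
    w <- which(occ_jk[, k])
    (max(w) - min(w) + 1) * map$spacing[2]
  }, numeric(1))
  kstar <- levels[which.max(ap)]   # ties -> lowest level
  (kstar - min(levels)) / (max(levels) - min(levels))
}

#' Tumour AP/SI aspect ratio
#'
#' Anteroposterior extent divided by supero-inferior extent. Ratios above
#' 1.1 mark the transverse growth pattern of S-type tumours.
#'
#' @param map A [label_map()] with tumour present.
#' @return Dimensionless ratio.
#' @export
aspect_ratio <- function(map) {
  ext <- tissue_extents(map, 1L)
  if (ext[["SI"]] <= 0)
    stop("tumor SI extent is zero: aspect ratio undefined", call. = FALSE)
  ext[["AP"]] / ext[["SI"]]
}

#' Names of the 34 clinical features, in canonical order
#'
#' @return Character vector of length 34.
#' @export
clinical_feature_names <- function() {
  tissues <- names(qst_labels())[-1]
  c(as.vector(t(outer(tissues, c("extent_lr_cm", "extent_ap_cm",
                                 "extent_si_cm"), paste, sep = "_"))),
    paste0(tissues, "_volume_cm3"),
    paste0("tumor_vs_brain_", c("lr", "ap", "si")),
    paste0("tumor_vs_sellar_", c("lr", "ap", "si")),
    "widest_level_fraction", "tumor_fossa_volume_cm3",
    "tumor_anterior_volume_cm3", "aspect_ratio_ap_si")
}

#' Extract the 34 clinical features from a label map
#'
#' Assembles, in a fixed documented order: 18 per-tissue extents (LR, AP,
#' SI for classes 1..6), 6 per-tissue volumes, 3 tumour-vs-brain position
#' components, 3 tumour-vs-sellar-landmark position components, the
#' widest-level fraction, the intrasellar (fossa) tumour volume, the
#' anterior tumour volume, and the AP/SI aspect ratio. Absent tissues give
#' zero extents/volumes; features whose reference is unavailable (no brain,
#' no sinus landmark) are `NA` and flagged in the `missing` attribute
#' rather than silently zeroed, since absence itself is diagnostic.
#'
#' @param map A [label_map()] with tumour present.
#' @return Named numeric vector of length 34, class `clinical_features`,
#'   with a logical `missing` attribute of the same length.
#' @export
extract_features <- function(map) {
  stopifnot(inherits(map, "label_map"))
  if (!any(map$voxels == 1L))
    stop("label map contains no tumor voxels", call. = FALSE)
  ext <- lapply(1:6, function(l) tissue_extents(map, l))
  vols <- vapply(1:6, function(l) tissue_volume(map, l), numeric(1))
  pos_brain <- relative_position(map, "brain")
  lm <- tryCatch(locate_tuberculum(map), error = function(e) NULL)
  pos_sellar <- relative_position(map, "landmark", lm = lm)
  fossa <- if (is.null(lm)) NA_real_ else tumor_fossa_volume(map, lm)
  anterior <- if (is.null(lm)) NA_real_ else tumor_anterior_volume(map, lm)
  feats <- c(unlist(ext), vols, pos_brain, pos_sellar,
             widest_level_fraction(map), fossa, anterior, aspect_ratio(map))
  names(feats) <- clinical_feature_names()
  structure(feats, missing = is.na(feats), class = "clinical_features")
}

#' @export
print.clinical_features <- function(x, ...) {
  cat("<clinical_features> 34 values (",
      sum(attr(x, "missing")), " missing)\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Feature table for a list of label maps
#'
#' @param maps List of [label_map()]s (or a `phantom_cohort`).
#' @param path Optional CSV output path.
#' @return Data frame with one row per map, 34 feature columns in canonical
#'   order (and `id`).
#' @export
feature_table <- function(maps, path = NULL) {
  if (inherits(maps, "phantom_cohort"))
    maps <- lapply(maps$samples, `[[`, "map")
  rows <- lapply(maps, function(m) as.vector(extract_features(m)))
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- clinical_feature_names()
  df <- cbind(id = seq_len(nrow(df)), df)
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
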