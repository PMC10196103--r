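#' @useDynLib sellarqst, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile sd
#' @importFrom utils read.csv write.csv modifyList
NULL

# Canonical array layout used throughout the package:
#   axis 1 (dim 1): left -> right, the sagittal slice stack
#   axis 2 (dim 2): posterior -> anterior
#   axis 3 (dim 3): inferior -> superior
# i.e. the "RAS" voxel order of the NIfTI world.

#' Tissue classes of the sellar-region label schema
#'
#' Seven integer classes cover the sellar region on contrast-enhanced
#' sagittal T1 MRI: background (0), tumour (1), pituitary gland together
#' with the stalk (2), sphenoid sinus including its bony wall (3), brain
#' (4), suprasellar cistern (5) and lateral ventricles (6). The suprasellar
#' cistern may be absent when effaced by tumour; the pituitary may be
#' invisible for infrasellar (Q-type) tumours.
#'
#' @return Named integer vector mapping class names to label values.
#' @export
#' @examples
#' qst_labels()
qst_labels <- function() {
  c(background = 0L, tumor = 1L, pituitary = 2L, sphenoid_sinus = 3L,
    brain = 4L, suprasellar_cistern = 5L, ventricle = 6L)
}

#' @rdname qst_labels
#' @return `qst_types()`: the three tumour subtypes, in tie-break priority
#'   order from lowest to highest (`T` outranks `S` outranks `Q`).
#' @export
qst_types <- function() c("Q", "S", "T")

#' Machine-readable description of the label schema
#'
#' Reads the JSON schema shipped with the package, listing each label value,
#' its name and an anatomical description.
#'
#' @return A data frame with columns `value`, `name`, `description`.
#' @export
label_schema <- function() {
  path <- system.file("extdata", "label_schema.json", package = "sellarqst")
  df <- jsonlite::fromJSON(path)$labels
  df$value <- as.integer(df$value)
  df
}

#' Construct a sellar label map
#'
#' A label map is a 3D integer array in canonical orientation (axis 1
#' left-right sagittal stack, axis 2 posterior-anterior, axis 3
#' inferior-superior) with voxel spacing in millimetres. Values must lie in
#' 0..6 per [qst_labels()].
#'
#' @param voxels 3D integer array of class indices.
#' @param spacing Numeric length-3 voxel edge lengths in mm. Default
#'   `c(6, 0.45, 0.45)`: 6 mm sagittal slice thickness, 0.45 mm in-plane.
#' @return An object of class `label_map`.
#' @export
label_map <- function(voxels, spacing = c(6, 0.45, 0.45)) {
  voxels <- validate_label_voxels(voxels)
  spacing <- validate_spacing(spacing)
  structure(list(voxels = voxels, spacing = spacing), class = "label_map")
}

#' Construct an MRI intensity volume
#'
#' @param voxels 3D numeric array of intensities, canonical orientation.
#' @param spacing Numeric length-3 voxel edge lengths in mm.
#' @return An object of class `mri_volume`.
#' @export
mri_volume <- function(voxels, spacing = c(6, 0.45, 0.45)) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  spacing <- validate_spacing(spacing)
  structure(list(voxels = voxels, spacing = spacing), class = "mri_volume")
}

validate_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive voxel edge lengths (mm)",
         call. = FALSE)
  spacing
}

validate_label_voxels <- function(voxels) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  v <- as.integer(voxels)
  if (anyNA(v) || any(v < 0L | v > 6L)) {
    bad <- unique(v[is.na(v) | v < 0L | v > 6L])
    stop("label values outside the 0..6 schema: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  array(v, dim = dim(voxels))
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = " x "), " mm\n",
      sep = "")
  tab <- tabulate(x$voxels + 1L, nbins = 7L)
  names(tab) <- names(qst_labels())
  print(tab[tab > 0])
  invisible(x)
}

#' @export
print.mri_volume <- function(x, ...) {
  cat("<mri_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = " x "), " mm\n",
      sep = "")
  invisible(x)
}

#' @export
dim.label_map <- function(x) dim(x$voxels)

#' @export
dim.mri_volume <- function(x) dim(x$voxels)

#' Read a NIfTI volume as a label map or intensity volume
#'
#' Reads a `.nii`/`.nii.gz` file, reorients it to the canonical axis order
#' when the header carries a usable orientation (qform/sform), and returns
#' either a validated [label_map()] or an [mri_volume()]. Voxel spacing is
#' taken from the header.
#'
#' @param path Path to a NIfTI file.
#' @param expect_labels If `TRUE`, values are validated against the 0..6
#'   schema and a `label_map` is returned; otherwise an `mri_volume`.
#' @param reorient Attempt reorientation to canonical order using header
#'   metadata (default `TRUE`). Files without orientation codes are assumed
#'   already canonical.
#' @return A `label_map` or `mri_volume`.
#' @export
read_volume <- function(path, expect_labels = FALSE, reorient = TRUE) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (reorient) {
    cur <- tryCatch(RNifti::orientation(img), warning = function(w) "RAS",
                    error = function(e) "RAS")
    if (!identical(cur, "RAS")) {
      img <- tryCatch({ RNifti::orientation(img) <- "RAS"; img },
                      warning = function(w) img, error = function(e) img)
    }
  }
  spacing <- abs(RNifti::pixdim(img)[1:3])
  vox <- as.array(img)
  vox <- array(as.vector(vox), dim = dim(vox)[1:3])
  if (expect_labels) {
    label_map(vox, spacing)
  } else {
    mri_volume(vox, spacing)
  }
}

#' Write a label map or MRI volume to NIfTI
#'
#' Label maps are stored as 16-bit integers so that labels round-trip
#' bit-exactly; intensity volumes as 32-bit floats.
#'
#' @param x A `label_map` or `mri_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "label_map") || inherits(x, "mri_volume"))
  dtype <- if (inherits(x, "label_map")) "int16" else "float"
  img <- RNifti::asNifti(x$voxels, datatype = dtype)
  img$pixdim <- c(-1, x$spacing, 1, 1, 1, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' One-hot encode a label map
#'
#' Expands a label map into a 4D binary array with one channel per class
#' (channel axis last, length 7). At every voxel exactly one channel is 1.
#' This is the representation the classification network consumes.
#'
#' @param map A [label_map()].
#' @return 4D 0/1 array with dim `c(dim(map), 7)`, class `one_hot_volume`.
#' @export
one_hot_encode <- function(map) {
  stopifnot(inherits(map, "label_map"))
  d <- dim(map$voxels)
  oh <- array(0L, dim = c(d, 7L))
  n <- prod(d)
  oh[seq_len(n) + n * as.vector(map$voxels)] <- 1L
  structure(oh, class = c("one_hot_volume", class(oh)))
}

#' Decode a one-hot volume back to a label map
#'
#' @param onehot A 4D one-hot array as produced by [one_hot_encode()].
#' @param spacing Voxel spacing for the reconstructed map.
#' @return A [label_map()].
#' @export
one_hot_decode <- function(onehot, spacing = c(6, 0.45, 0.45)) {
  d <- dim(onehot)
  stopifnot(length(d) == 4L, d[4] == 7L)
  n <- prod(d[1:3])
  m <- matrix(as.vector(onehot), nrow = n, ncol = 7L)
  label_map(array(max.col(m, ties.method = "first") - 1L, dim = d[1:3]),
            spacing)
}

#' Sagittal slice with the largest tumour cross-section
#'
#' Returns the index along the sagittal stack (axis 1) whose 2D slice holds
#' the most tumour voxels; ties are broken towards the smallest index. This
#' is the slice the classification network consumes.
#'
#' @param map A [label_map()] containing at least one tumour voxel.
#' @return Integer slice index.
#' @export
select_max_tumor_slice <- function(map) {
  stopifnot(inherits(map, "label_map"))
  counts <- apply(map$voxels == 1L, 1L, sum)
  if (sum(counts) == 0L)
    stop("label map contains no tumor voxels", call. = FALSE)
  which.max(counts)  # ties -> smallest index
}
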