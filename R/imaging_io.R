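# Volume I/O and the minimal preprocessing applied before age prediction:
# min-max intensity normalization over the brain mask and (optional) linear
# resampling onto a template grid. Phantoms are generated pre-registered and
# skull-stripped, so the brain mask is simply labels > 0.

#' Labeled 3D volume
#'
#' Pairs an intensity grid with an integer tissue-label grid of the same
#' shape (codes in [TISSUE_LABELS]) and carries the voxel size in mm.
#'
#' @param intensities Numeric 3D array (arbitrary units).
#' @param labels Integer 3D array with codes 0-5.
#' @param voxel_size Numeric length-3, mm per axis.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(intensities, labels, voxel_size) {
  stopifnot(identical(dim(intensities), dim(labels)),
            length(dim(intensities)) == 3, length(voxel_size) == 3)
  if (!all(labels %in% 0:5)) stop("invalid label codes", call. = FALSE)
  structure(list(intensities = intensities,
                 labels = array(as.integer(labels), dim = dim(labels)),
                 voxel_size = as.numeric(voxel_size)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("<labeled_volume> ", paste(dim(x$intensities), collapse = "x"),
      " voxels at ", paste(x$voxel_size, collapse = "x"), " mm; brain mask ",
      sum(x$labels > 0), " voxels\n", sep = "")
  invisible(x)
}

#' Write / read a labeled volume as NIfTI-1 pairs
#'
#' The intensity image goes to `path` (conventionally `<id>_t1.nii.gz`) and
#' the label companion to the same name with `_t1` replaced by `_labels`
#' (or `_labels` appended before the extension). Voxel sizes are stored in
#' the NIfTI header and restored on read.
#'
#' @param vol A [labeled_volume()].
#' @param path Path of the intensity NIfTI (.nii or .nii.gz).
#' @return `read_labeled_volume` returns a [labeled_volume()].
#' @export
write_labeled_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$intensities)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path)
  lab <- RNifti::asNifti(array(vol$labels, dim = dim(vol$labels)))
  RNifti::pixdim(lab) <- vol$voxel_size
  RNifti::writeNifti(lab, labels_path(path), datatype = "int16")
  invisible(path)
}

#' @rdname write_labeled_volume
#' @export
read_labeled_volume <- function(path) {
  img <- RNifti::readNifti(path)
  lab <- RNifti::readNifti(labels_path(path))
  labeled_volume(array(as.numeric(img), dim = dim(img)),
                 array(as.integer(lab), dim = dim(lab)),
                 RNifti::pixdim(img)[1:3])
}

labels_path <- function(path) {
  if (grepl("_t1\\.nii(\\.gz)?$", path))
    sub("_t1\\.nii", "_labels.nii", path)
  else sub("\\.nii", "_labels.nii", path)
}

#' Min-max intensity normalization over a mask
#'
#' Rescales masked voxels to `[0, 1]` via `(v - min) / (max - min)` computed
#' over the mask; voxels outside the mask are set to 0. Idempotent on its own
#' output.
#'
#' @param volume Numeric 3D array.
#' @param mask Logical array of the same shape (e.g. `labels > 0`); must
#'   select at least one voxel.
#' @return Numeric array in `[0, 1]`.
#' @export
minmax_normalize <- function(volume, mask) {
  stopifnot(identical(dim(volume), dim(mask)))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  v <- volume[mask]
  rng <- range(v)
  if (rng[2] <= rng[1])
    stop("degenerate image: constant intensity over the mask", call. = FALSE)
  out <- array(0, dim = dim(volume))
  out[mask] <- (v - rng[1]) / (rng[2] - rng[1])
  out
}

#' Affine resampling onto a target grid
#'
#' `affine` is a 4x4 matrix mapping 0-based target voxel indices
#' (homogeneous) to 0-based source voxel coordinates. Intensities should use
#' trilinear interpolation and label maps nearest-neighbour; voxels mapping
#' outside the source field of view are 0.
#'
#' @param volume Numeric 3D array.
#' @param affine Invertible 4x4 numeric matrix.
#' @param target_shape Integer length-3.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return Numeric 3D array of shape `target_shape`.
#' @export
resample_affine <- function(volume, affine, target_shape,
                            interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) stop("singular affine", call. = FALSE)
  cpp_affine_resample(as.numeric(volume), dim(volume), affine,
                      as.integer(target_shape),
                      if (interpolation == "nearest") 1L else 0L)
}

#' Tissue volumetry from a label map
#'
#' Computes the standard structural report from a labeled volume: gray
#' matter, white matter and CSF as percent of intracranial volume (ICV =
#' labels 1-5), and the WMH lesion burden in mL. CSF pools the sulcal and
#' ventricular compartments (one CSF number is reported); WMH voxels are
#' counted inside white matter for the WM percentage (lesions are
#' white-matter tissue) and additionally reported in mL, so
#' `gm + wm + csf = 100` exactly.
#'
#' @param vol A [labeled_volume()].
#' @return List of class `volumetry_record`: `gm_pct_icv`, `wm_pct_icv`,
#'   `csf_pct_icv`, `wmh_ml`, `icv_ml`.
#' @export
tissue_fractions <- function(vol) {
  lab <- vol$labels
  counts <- tabulate(lab + 1L, nbins = 6L)  # labels 0..5
  icv <- sum(counts[2:6])
  if (icv == 0) stop("empty brain mask", call. = FALSE)
  vox_ml <- prod(vol$voxel_size) / 1000
  structure(list(
    gm_pct_icv = 100 * counts[3] / icv,
    wm_pct_icv = 100 * (counts[4] + counts[6]) / icv,
    csf_pct_icv = 100 * (counts[2] + counts[5]) / icv,
    wmh_ml = counts[6] * vox_ml,
    icv_ml = icv * vox_ml
  ), class = "volumetry_record")
}

#' Volumetry table for a whole cohort
#'
#' @param volumes Named list of [labeled_volume()] (names are subject ids).
#' @param path Optional CSV path (`id,gm_pct,wm_pct,csf_pct,wmh_ml`).
#' @return data.frame with one row per subject.
#' @export
volumetry_table <- function(volumes, path = NULL) {
  rows <- lapply(names(volumes), function(id) {
    fr <- tissue_fractions(volumes[[id]])
    data.frame(id = id, gm_pct = fr$gm_pct_icv, wm_pct = fr$wm_pct_icv,
               csf_pct = fr$csf_pct_icv, wmh_ml = fr$wmh_ml,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Preprocess a labeled volume for the age regressor
#'
#' The minimal pipeline applied before prediction: min-max normalization over
#' the brain mask (labels > 0). Phantoms are generated on the template grid,
#' so no registration resampling is required; use [resample_affine()] when a
#' volume arrives on a different grid.
#'
#' @param vol A [labeled_volume()].
#' @return Numeric 3D array in `[0, 1]`.
#' @export
preprocess_volume <- function(vol) {
  minmax_normalize(vol$intensities, vol$labels > 0)
}
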