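# Occlusion-sensitivity attention maps: slide a cubic mask over the input,
# re-predict with the masked region hidden, and accumulate |prediction shift|
# over the voxels each mask covered. The result localizes the evidence the
# age regressor relies on, without gradients.

#' Occlusion configuration
#'
#' @param mask_size Integer length-1 or -3, mask edge in voxels (default
#'   8^3).
#' @param stride Mask step in voxels; defaults to `mask_size`
#'   (non-overlapping). Smaller strides overlap; coverage normalization then
#'   divides each voxel by the number of masks that covered it.
#' @param fill_value Intensity used to hide a region (0 = the background
#'   value after min-max normalization).
#' @param normalize_overlap Divide accumulated weights by per-voxel coverage.
#' @return Object of class `occlusion_config`.
#' @export
occlusion_config <- function(mask_size = 8L, stride = mask_size,
                             fill_value = 0, normalize_overlap = TRUE) {
  mask_size <- as.integer(rep_len(mask_size, 3))
  stride <- as.integer(rep_len(stride, 3))
  stopifnot(all(mask_size >= 1), all(stride >= 1))
  structure(list(mask_size = mask_size, stride = stride,
                 fill_value = fill_value,
                 normalize_overlap = isTRUE(normalize_overlap)),
            class = "occlusion_config")
}

# Mask start indices along one axis (1-based, fully inside the grid).
occlusion_starts <- function(n, mask, stride) {
  if (mask > n) stop("occlusion mask larger than volume", call. = FALSE)
  seq.int(1L, n - mask + 1L, by = stride)
}

#' Occlusion-sensitivity attention map for one volume
#'
#' For every placement of the mask on the stride lattice, the occluded
#' volume is re-predicted and the placement's weight is the absolute
#' prediction shift |predict(masked) - predict(original)| in years. The map
#' is the weight-weighted sum of the binary mask indicators, optionally
#' divided by per-voxel coverage.
#'
#' @param model A trained `age_model`.
#' @param volume Preprocessed 3D array (same grid as the model input).
#' @param config An [occlusion_config()].
#' @param subject_id Tag stored on the map.
#' @return Object of class `attention_map`: `weights` (non-negative array of
#'   the input shape), `subject_id`, `n_placements`.
#' @export
occlusion_map <- function(model, volume, config = occlusion_config(),
                          subject_id = NA_character_) {
  dims <- dim(volume)
  starts <- mapply(occlusion_starts, dims, config$mask_size, config$stride,
                   SIMPLIFY = FALSE)
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  n_pl <- nrow(grid)

  base <- predict_age(model, volume)
  masked <- matrix(as.numeric(volume), length(volume), n_pl)
  for (p in seq_len(n_pl)) {
    idx <- as.matrix(expand.grid(
      grid$x[p]:(grid$x[p] + config$mask_size[1] - 1L),
      grid$y[p]:(grid$y[p] + config$mask_size[2] - 1L),
      grid$z[p]:(grid$z[p] + config$mask_size[3] - 1L)))
    flat <- idx[, 1] + dims[1] * (idx[, 2] - 1L) +
      dims[1] * dims[2] * (idx[, 3] - 1L)
    masked[flat, p] <- config$fill_value
  }
  preds <- predict_age(model, masked)
  w <- abs(preds - base)

  weights <- array(0, dim = dims)
  coverage <- array(0L, dim = dims)
  for (p in seq_len(n_pl)) {
    xs <- grid$x[p]:(grid$x[p] + config$mask_size[1] - 1L)
    ys <- grid$y[p]:(grid$y[p] + config$mask_size[2] - 1L)
    zs <- grid$z[p]:(grid$z[p] + config$mask_size[3] - 1L)
    weights[xs, ys, zs] <- weights[xs, ys, zs] + w[p]
    coverage[xs, ys, zs] <- coverage[xs, ys, zs] + 1L
  }
  if (config$normalize_overlap)
    weights[coverage > 0] <- weights[coverage > 0] / coverage[coverage > 0]
  structure(list(weights = weights, subject_id = subject_id,
                 n_placements = n_pl),
            class = "attention_map")
}

#' @export
print.attention_map <- function(x, ...) {
  cat("<attention_map> ", paste(dim(x$weights), collapse = "x"),
      " (", x$subject_id, "), ", x$n_placements,
      " placements, total weight ", signif(sum(x$weights), 4), "\n", sep = "")
  invisible(x)
}

#' Population-average attention map
#'
#' Voxelwise arithmetic mean of per-subject maps, tagged `"population"`.
#' @param maps Non-empty list of [occlusion_map()] results of equal shape.
#' @return An `attention_map`.
#' @export
average_maps <- function(maps) {
  if (length(maps) == 0) stop("no maps to average", call. = FALSE)
  dims <- dim(maps[[1]]$weights)
  acc <- array(0, dim = dims)
  for (m in maps) {
    stopifnot(identical(dim(m$weights), dims))
    acc <- acc + m$weights
  }
  structure(list(weights = acc / length(maps), subject_id = "population",
                 n_placements = maps[[1]]$n_placements),
            class = "attention_map")
}

#' Attention localization ratio
#'
#' Mean attention weight inside the age-signal tissue (ventricular CSF and
#' the gray-matter ribbon, where the generator injects age-dependent
#' morphology) divided by the mean weight over the background shell outside
#' the brain mask. Values well above 1 mean the regressor's evidence
#' concentrates where the age signal lives.
#'
#' @param map An `attention_map`.
#' @param labels Integer label array on the same grid.
#' @return List: `signal_mean`, `background_mean`, `ratio`.
#' @export
attention_region_ratio <- function(map, labels) {
  stopifnot(identical(dim(map$weights), dim(labels)))
  sig <- labels %in% TISSUE_LABELS[c("ventricle", "gm")]
  bg <- labels == TISSUE_LABELS[["background"]]
  s <- mean(map$weights[sig]); b <- mean(map$weights[bg])
  list(signal_mean = s, background_mean = b,
       ratio = if (b > 0) s / b else Inf)
}

#' Export an attention map as NIfTI
#' @param map An `attention_map`.
#' @param path Output .nii/.nii.gz path.
#' @param voxel_size mm per axis.
#' @return Invisibly, the path.
#' @export
write_attention_map <- function(map, path, voxel_size = c(5, 5, 5)) {
  RNifti::writeNifti(RNifti::asNifti(map$weights, pixdim = voxel_size), path)
  invisible(path)
}
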