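# Synthetic aging-brain cohort generator. The phantom is deliberately not an
# anatomy model: concentric ellipsoids make every ground-truth tissue volume
# computable, which is what downstream tests need. Aging enters only through
# ventricular growth, gray-matter thinning and the WMH rate.

# Normalized ellipsoidal radius field (r = 1 on the brain boundary),
# in R array order, for voxel centres.
ellipsoid_radius_field <- function(spec) {
  n <- spec$grid_shape
  ctr <- (n + 1) / 2
  ax <- (seq_len(n[1]) - ctr[1]) / spec$brain_semiaxes[1]
  ay <- (seq_len(n[2]) - ctr[2]) / spec$brain_semiaxes[2]
  az <- (seq_len(n[3]) - ctr[3]) / spec$brain_semiaxes[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  sqrt(r2)
}

# Age-dependent tissue budget in analytic voxels and the corresponding
# fractional-radius thresholds of the concentric structure.
phantom_thresholds <- function(effective_age, spec) {
  v <- analytic_brain_volume(spec)
  years <- effective_age - 18
  vent <- spec$ventricle_base_volume + spec$ventricle_growth * years
  gm <- max(spec$gm_ribbon_base - spec$gm_thinning * years, 1)
  r_vent <- (vent / v)^(1 / 3)
  r_wm <- (spec$wm_outer_volume / v)^(1 / 3)
  r_gm <- ((spec$wm_outer_volume + gm) / v)^(1 / 3)
  if (r_gm >= 1 || vent >= spec$wm_outer_volume)
    stop("phantom structure does not fit at effective age ", effective_age,
         call. = FALSE)
  list(r_vent = r_vent, r_wm = r_wm, r_gm = r_gm,
       volumes = c(ventricle = vent, gm = gm))
}

#' Generate one labeled phantom volume
#'
#' Builds the concentric-ellipsoid brain at a given effective age (outer
#' sulcal-CSF shell, gray-matter ribbon, white-matter core, central
#' ventricles), drops Poisson-sampled WMH lesions into the white matter, and
#' adds Gaussian intensity noise inside the brain mask. The label grid is
#' noise-free; the pre-noise structure is a deterministic function of
#' effective age, so ventricle volume rises and gray matter falls
#' monotonically with age.
#'
#' @param effective_age Years, in `[18, 80]` (chronological age + aging offset).
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; WMH placement and intensity noise are drawn from
#'   substreams of it, so identical `(effective_age, spec, seed)` reproduce the
#'   volume bit-for-bit.
#' @param wmh_multiplier Multiplier on the WMH rate (used for disease
#'   surrogates; see `phantom_spec()$wmh_disease_multiplier`).
#' @return A [labeled_volume()].
#' @export
generate_subject_volume <- function(effective_age, spec = phantom_spec(),
                                    seed = 1L, wmh_multiplier = 1) {
  stopifnot(effective_age >= 18, effective_age <= 80)
  th <- phantom_thresholds(effective_age, spec)
  r <- ellipsoid_radius_field(spec)

  labels <- array(TISSUE_LABELS[["background"]], dim = spec$grid_shape)
  labels[r <= 1] <- TISSUE_LABELS[["csf"]]
  labels[r < th$r_gm] <- TISSUE_LABELS[["gm"]]
  labels[r < th$r_wm] <- TISSUE_LABELS[["wm"]]
  labels[r < th$r_vent] <- TISSUE_LABELS[["ventricle"]]

  # WMH: expected count grows with effective age beyond 30; lesions are small
  # spheres clipped to the white matter so they never touch the brain edge.
  lambda <- spec$wmh_rate * max(0, effective_age - 30) * wmh_multiplier
  if (lambda > 0) {
    labels <- with_seed(substream_seed(seed, "wmh"), {
      n_les <- rpois(1, lambda)
      if (n_les > 0) {
        wm_idx <- which(labels == TISSUE_LABELS[["wm"]])
        dims <- spec$grid_shape
        for (i in seq_len(n_les)) {
          centre_flat <- wm_idx[sample.int(length(wm_idx), 1)]
          centre <- arrayInd(centre_flat, dims)
          radius <- runif(1, spec$wmh_radius_range[1], spec$wmh_radius_range[2])
          rr <- ceiling(radius)
          xs <- max(1, centre[1] - rr):min(dims[1], centre[1] + rr)
          ys <- max(1, centre[2] - rr):min(dims[2], centre[2] + rr)
          zs <- max(1, centre[3] - rr):min(dims[3], centre[3] + rr)
          for (z in zs) for (y in ys) for (x in xs) {
            if (sqrt(sum((c(x, y, z) - centre)^2)) <= radius &&
                labels[x, y, z] == TISSUE_LABELS[["wm"]])
              labels[x, y, z] <- TISSUE_LABELS[["wmh"]]
          }
        }
      }
      labels
    })
  }

  mu <- c(0, spec$tissue_intensity_means[c("csf", "gm", "wm",
                                           "ventricle", "wmh")])
  intens <- array(mu[labels + 1L], dim = spec$grid_shape)
  if (spec$noise_sd > 0) {
    mask <- labels > 0
    intens[mask] <- intens[mask] +
      with_seed(substream_seed(seed, "noise"),
                rnorm(sum(mask), 0, spec$noise_sd))
  }
  labeled_volume(intens, labels, spec$voxel_size)
}

#' Sample per-subject covariates
#'
#' Attaches plasma log10-NfL and the five standardized cognitive scores to a
#' subject record. `log_nfl = intercept + slope_age * chronological_age +
#' slope_offset * delta + N(0, noise_sd)`; each cognitive score is
#' `base - slope_offset_domain * delta + N(0, sd)`. Scores are unbounded; a
#' warning is emitted when any falls outside [40, 160].
#'
#' @param record List or one-row data.frame with `chronological_age` and
#'   `offset_delta`.
#' @param cohort A [cohort_spec()] carrying the covariate models.
#' @param seed Integer seed for the covariate draw.
#' @return `record` with `log_nfl` and the five domain scores added.
#' @export
sample_covariates <- function(record, cohort, seed = 1L) {
  stopifnot(!is.null(record$chronological_age), !is.null(record$offset_delta))
  nm <- cohort$nfl_model
  cg <- cohort$cognition_model
  domains <- cognitive_domains()
  with_seed(seed, {
    record$log_nfl <- nm$intercept +
      nm$slope_per_year_age * record$chronological_age +
      nm$slope_per_year_offset * record$offset_delta +
      rnorm(1, 0, nm$noise_sd)
    for (d in domains) {
      val <- cg$base - cg$slope_per_year_offset[[d]] * record$offset_delta +
        rnorm(1, 0, cg$sd)
      if (val < 40 || val > 160)
        warning("cognitive score ", d, " = ", round(val, 1),
                " outside [40, 160]", call. = FALSE)
      record[[d]] <- val
    }
  })
  record
}

# Truncated-normal age draw clipped to a range.
sample_ages <- function(n, mean_sd, range) {
  pmin(pmax(rnorm(n, mean_sd[1], mean_sd[2]), range[1]), range[2])
}

#' Generate a full synthetic cohort
#'
#' Samples training, control and patient subjects per the [cohort_spec()],
#' builds each subject's labeled volume at their effective age (chronological
#' age for training/controls, chronological + offset for patients), samples
#' covariates, and optionally writes NIfTI volume pairs
#' (`<id>_t1.nii.gz`, `<id>_labels.nii.gz`) plus a manifest CSV to `dir`.
#'
#' All randomness flows from `cohort$seed` through named substreams (ages,
#' per-subject structure/noise, covariates), so the same specs reproduce the
#' manifest and volumes exactly.
#'
#' @param cohort A [cohort_spec()].
#' @param spec A [phantom_spec()].
#' @param dir Output directory; created if needed. `NULL` keeps everything
#'   in memory.
#' @param keep_volumes Return the volumes in the result (default `TRUE`).
#' @return List with `manifest` (data.frame: id, role, chronological_age,
#'   offset_delta, effective_age, log_nfl, five cognitive columns,
#'   volume_path) and, if `keep_volumes`, `volumes` (named list of
#'   [labeled_volume()]).
#' @export
generate_cohort <- function(cohort, spec = phantom_spec(), dir = NULL,
                            keep_volumes = TRUE) {
  root <- cohort$seed
  n_tot <- cohort$n_training + cohort$n_controls + cohort$n_patients
  stopifnot(n_tot >= 1)

  ages <- with_seed(substream_seed(root, "ages"), {
    tr <- runif(cohort$n_training, cohort$training_age_range[1],
                cohort$training_age_range[2])
    ct <- sample_ages(cohort$n_controls, cohort$control_age_mean_sd,
                      cohort$study_age_range)
    pt <- sample_ages(cohort$n_patients, cohort$patient_age_mean_sd,
                      cohort$study_age_range)
    dl <- rnorm(cohort$n_patients, cohort$offset_mean_sd[1],
                cohort$offset_mean_sd[2])
    if (!cohort$allow_negative_offset) dl <- pmax(dl, 0)
    list(tr = tr, ct = ct, pt = pt, dl = dl)
  })

  man <- data.frame(
    id = c(sprintf("train%03d", seq_len(cohort$n_training)),
           sprintf("ctrl%03d", seq_len(cohort$n_controls)),
           sprintf("pat%03d", seq_len(cohort$n_patients))),
    role = rep(c("training", "control", "patient"),
               c(cohort$n_training, cohort$n_controls, cohort$n_patients)),
    chronological_age = c(ages$tr, ages$ct, ages$pt),
    offset_delta = c(rep(0, cohort$n_training + cohort$n_controls), ages$dl),
    stringsAsFactors = FALSE
  )
  man$effective_age <- man$chronological_age + man$offset_delta

  for (d in c("log_nfl", cognitive_domains())) man[[d]] <- NA_real_
  for (i in seq_len(nrow(man))) {
    rec <- sample_covariates(as.list(man[i, ]), cohort,
                             seed = substream_seed(root, "covariates", i))
    man$log_nfl[i] <- rec$log_nfl
    for (d in cognitive_domains()) man[[d]][i] <- rec[[d]]
  }

  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  volumes <- if (keep_volumes) vector("list", nrow(man)) else NULL
  man$volume_path <- NA_character_
  for (i in seq_len(nrow(man))) {
    mult <- if (man$offset_delta[i] > 0) spec$wmh_disease_multiplier else 1
    vol <- generate_subject_volume(man$effective_age[i], spec,
                                   seed = substream_seed(root, "structure", i),
                                   wmh_multiplier = mult)
    if (!is.null(dir)) {
      man$volume_path[i] <- file.path(dir, paste0(man$id[i], "_t1.nii.gz"))
      write_labeled_volume(vol, man$volume_path[i])
    }
    if (keep_volumes) volumes[[i]] <- vol
  }
  if (keep_volumes) names(volumes) <- man$id
  if (!is.null(dir)) write_manifest(man, file.path(dir, "manifest.csv"))
  res <- list(manifest = man)
  if (keep_volumes) res$volumes <- volumes
  res
}

#' Write / read a cohort manifest CSV
#'
#' The on-disk header is `id,role,chronological_age,offset_delta,log_nfl,`
#' the five cognitive columns, `,volume_path`; `effective_age` is
#' reconstructed on read as chronological age + offset.
#' @param manifest Manifest data.frame from [generate_cohort()].
#' @param path CSV path.
#' @return `read_manifest` returns the manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("id", "role", "chronological_age", "offset_delta", "log_nfl",
            cognitive_domains(), "volume_path")
  write.csv(manifest[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  man$effective_age <- man$chronological_age + man$offset_delta
  man
}
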