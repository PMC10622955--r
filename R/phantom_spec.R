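#' Phantom geometry specification
#'
#' Describes the concentric-ellipsoid aging-brain phantom: an outer sulcal-CSF
#' shell, a gray-matter ribbon, a white-matter core and central ventricles,
#' plus small hyperintense WMH lesions. Aging is encoded as deterministic
#' ventricular growth and gray-matter thinning (sulcal CSF fills the eroded
#' ribbon); all other structure is age-invariant. Geometry is parameterised in
#' voxel counts of the analytic ellipsoid so ground-truth tissue fractions are
#' computable in closed form.
#'
#' Defaults are calibrated so that a control cohort (mean age about 37 y)
#' has mean tissue fractions near GM 52.3, WM 36.9 and CSF 10.8 percent of
#' intracranial volume, with a mean WMH burden of about 0.06 mL.
#'
#' @param grid_shape Integer length-3, voxels per axis (each >= 16).
#' @param voxel_size Numeric length-3, mm per axis. The default 5 mm gives a
#'   desk-scale 32^3 grid an intracranial volume of about 1.3 L.
#' @param brain_semiaxes Numeric length-3, ellipsoid semi-axes in voxels.
#' @param ventricle_base_volume Ventricle volume in voxels at age 18.
#' @param ventricle_growth Ventricle growth, voxels per year of effective age.
#' @param gm_ribbon_base Gray-matter ribbon volume in voxels at age 18.
#' @param gm_thinning Gray-matter loss, voxels per year of effective age.
#' @param wm_outer_volume Volume in voxels enclosed by the (age-invariant)
#'   outer white-matter boundary; white matter itself is this minus the
#'   ventricles.
#' @param tissue_intensity_means Named numeric map tissue -> mean intensity
#'   (arbitrary units) with names csf, gm, wm, ventricle, wmh.
#' @param noise_sd Additive Gaussian intensity noise SD (arbitrary units),
#'   applied inside the brain mask only; labels stay noise-free.
#' @param wmh_rate Expected WMH lesion count per year of effective age
#'   beyond 30.
#' @param wmh_radius_range Numeric length-2, lesion radius range in voxels.
#' @param wmh_disease_multiplier Multiplier applied to `wmh_rate` for subjects
#'   carrying a positive aging offset (disease surrogate).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         voxel_size = c(5, 5, 5),
                         brain_semiaxes = c(13, 15, 13),
                         ventricle_base_volume = 212,
                         ventricle_growth = 5.6,
                         gm_ribbon_base = 5734,
                         gm_thinning = 9.5,
                         wm_outer_volume = 4237,
                         tissue_intensity_means = c(csf = 30, gm = 70, wm = 100,
                                                    ventricle = 30, wmh = 130),
                         noise_sd = 5,
                         wmh_rate = 0.025,
                         wmh_radius_range = c(0.5, 1.2),
                         wmh_disease_multiplier = 2) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, length(voxel_size) == 3,
            length(brain_semiaxes) == 3, length(wmh_radius_range) == 2)
  spec <- structure(list(
    grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
    brain_semiaxes = as.numeric(brain_semiaxes),
    ventricle_base_volume = ventricle_base_volume,
    ventricle_growth = ventricle_growth,
    gm_ribbon_base = gm_ribbon_base, gm_thinning = gm_thinning,
    wm_outer_volume = wm_outer_volume,
    tissue_intensity_means = tissue_intensity_means,
    noise_sd = noise_sd, wmh_rate = wmh_rate,
    wmh_radius_range = as.numeric(wmh_radius_range),
    wmh_disease_multiplier = wmh_disease_multiplier
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  if (any(spec$grid_shape < 16L))
    stop("grid_shape components must be >= 16", call. = FALSE)
  if (spec$ventricle_growth <= 0)
    stop("ventricle_growth must be > 0", call. = FALSE)
  if (spec$gm_thinning < 0) stop("gm_thinning must be >= 0", call. = FALSE)
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(spec$voxel_size <= 0)) stop("voxel_size must be > 0", call. = FALSE)
  if (any(spec$brain_semiaxes >= spec$grid_shape / 2))
    stop("brain_semiaxes must fit inside grid_shape", call. = FALSE)
  needed <- c("csf", "gm", "wm", "ventricle", "wmh")
  if (!all(needed %in% names(spec$tissue_intensity_means)))
    stop("tissue_intensity_means must name: ",
         paste(needed, collapse = ", "), call. = FALSE)
  v <- analytic_brain_volume(spec)
  # tissue budget must fit inside the brain at the oldest supported age (80)
  worst <- spec$ventricle_base_volume + 62 * spec$ventricle_growth
  if (spec$wm_outer_volume + spec$gm_ribbon_base >= v ||
      worst >= spec$wm_outer_volume)
    stop("tissue volumes do not fit inside the brain ellipsoid across ",
         "ages 18-80; shrink growth/thinning rates or enlarge the brain",
         call. = FALSE)
  spec
}

# Analytic ellipsoid volume in voxels.
analytic_brain_volume <- function(spec) {
  4 / 3 * pi * prod(spec$brain_semiaxes)
}

#' Cohort sampling specification
#'
#' Sampling rules for a synthetic study: a training set of healthy subjects
#' spanning the training age range, a control group and a patient group with
#' an injectable disease-related aging offset delta (years). Patients' volumes
#' are generated at effective age = chronological age + delta; training
#' subjects and controls have delta = 0. The covariate model couples plasma
#' log10 NfL to age and to delta, and shifts cognitive scores (normed to mean
#' 100, SD 15) downward with delta.
#'
#' Defaults mirror the reference SLE study population: female cohorts, study
#' ages 18-55 with patients 35.9 (SD 9.0) and controls 37.0 (SD 9.4) years,
#' training ages 18-70, and an aging offset averaging 4 years.
#'
#' @param n_training,n_controls,n_patients Group sizes.
#' @param training_age_range,study_age_range Age ranges in years; sampled ages
#'   are clipped to these.
#' @param control_age_mean_sd,patient_age_mean_sd Normal age models (years).
#' @param offset_mean_sd Aging-offset delta model (years); negative draws are
#'   truncated to 0 unless `allow_negative_offset`.
#' @param allow_negative_offset Permit "younger-looking" patients.
#' @param nfl_model List: intercept, slope_per_year_age, slope_per_year_offset,
#'   noise_sd, on the log10 pg/mL scale.
#' @param cognition_model List: base (100), sd (15), and
#'   slope_per_year_offset, a named vector over the five cognitive domains
#'   (points lost per year of delta).
#' @param seed Integer root seed for all of the cohort's substreams.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_training = 200L, n_controls = 24L, n_patients = 70L,
                        training_age_range = c(18, 70),
                        study_age_range = c(18, 55),
                        control_age_mean_sd = c(37.0, 9.4),
                        patient_age_mean_sd = c(35.9, 9.0),
                        offset_mean_sd = c(4, 2),
                        allow_negative_offset = FALSE,
                        nfl_model = list(intercept = 0.55,
                                         slope_per_year_age = 0.005,
                                         slope_per_year_offset = 0.02,
                                         noise_sd = 0.13),
                        cognition_model = list(
                          base = 100, sd = 15,
                          slope_per_year_offset = c(
                            composite_memory = 0.5,
                            psychomotor_speed = 1.5,
                            reaction_time = 2.5,
                            complex_attention = 1.0,
                            cognitive_flexibility = 1.5)),
                        seed = 1L) {
  stopifnot(n_training >= 0, n_controls >= 0, n_patients >= 0)
  if (!identical(sort(names(cognition_model$slope_per_year_offset)),
                 sort(cognitive_domains())))
    stop("cognition_model$slope_per_year_offset must name exactly the five ",
         "cognitive domains", call. = FALSE)
  structure(list(
    n_training = as.integer(n_training), n_controls = as.integer(n_controls),
    n_patients = as.integer(n_patients),
    training_age_range = training_age_range,
    study_age_range = study_age_range,
    control_age_mean_sd = control_age_mean_sd,
    patient_age_mean_sd = patient_age_mean_sd,
    offset_mean_sd = offset_mean_sd,
    allow_negative_offset = isTRUE(allow_negative_offset),
    nfl_model = nfl_model, cognition_model = cognition_model,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' The five cognitive domains recorded per subject
#' @return Character vector of domain names.
#' @export
cognitive_domains <- function() {
  c("composite_memory", "psychomotor_speed", "reaction_time",
    "complex_attention", "cognitive_flexibility")
}

#' Read a phantom/cohort configuration from YAML
#'
#' The YAML file may contain top-level `phantom:` and `cohort:` blocks whose
#' fields mirror the arguments of [phantom_spec()] and [cohort_spec()].
#' @param path YAML file path.
#' @return List with elements `phantom` and `cohort`.
#' @export
read_spec_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  ph <- do.call(phantom_spec, raw$phantom %||% list())
  co <- do.call(cohort_spec, raw$cohort %||% list())
  list(phantom = ph, cohort = co)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n",
      " grid ", paste(x$grid_shape, collapse = "x"),
      " voxels at ", paste(x$voxel_size, collapse = "x"), " mm\n",
      " ICV (analytic) ", round(analytic_brain_volume(x)), " voxels\n",
      " ventricles ", x$ventricle_base_volume, " vox @18y, +",
      x$ventricle_growth, " vox/y; GM ", x$gm_ribbon_base, " vox @18y, -",
      x$gm_thinning, " vox/y\n", sep = "")
  invisible(x)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> training n=", x$n_training, ", controls n=",
      x$n_controls, ", patients n=", x$n_patients,
      ", offset ~ N(", x$offset_mean_sd[1], ", ", x$offset_mean_sd[2],
      "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}
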