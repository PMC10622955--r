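# Synthetic cohort generator: determinism, aging monotonicity, covariate
# model, and calibration of the default control tissue fractions.

test_that("volume generation is bit-identical under a fixed seed", {
  spec <- tiny_phantom()
  v1 <- generate_subject_volume(45, spec, seed = 9)
  v2 <- generate_subject_volume(45, spec, seed = 9)
  expect_identical(v1, v2)
  v3 <- generate_subject_volume(45, spec, seed = 10)
  expect_false(identical(v1$intensities, v3$intensities))
})

test_that("aging is monotone: ventricles grow, gray matter thins (noise-free labels)", {
  spec <- phantom_spec()
  ages <- seq(20, 70, by = 5)
  vent <- vapply(ages, function(a)
    sum(generate_subject_volume(a, spec, seed = 2)$labels ==
          TISSUE_LABELS[["ventricle"]]), 0)
  gm <- vapply(ages, function(a)
    sum(generate_subject_volume(a, spec, seed = 2)$labels ==
          TISSUE_LABELS[["gm"]]), 0)
  expect_true(all(diff(vent) > 0))
  expect_true(all(diff(gm) < 0))
  expect_gt(vent[length(vent)], vent[1])
})

test_that("phantom structure is concentric and WMH stays inside white matter", {
  spec <- phantom_spec()
  v <- generate_subject_volume(65, spec, seed = 3, wmh_multiplier = 20)
  expect_setequal(unique(as.vector(v$labels)),
                  c(0L, 1L, 2L, 3L, 4L, 5L))
  # every WMH voxel has all 6-neighbours inside the brain mask
  wmh <- which(v$labels == TISSUE_LABELS[["wmh"]], arr.ind = TRUE)
  expect_gt(nrow(wmh), 0)
  mask <- v$labels > 0
  for (k in seq_len(nrow(wmh))) {
    p <- wmh[k, ]
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      q <- p + d
      expect_true(mask[q[1], q[2], q[3]])
    }
  }
  # labels are noise-free: regenerating with a different noise realization
  # (same structural seed) keeps labels identical
  spec2 <- spec; spec2$noise_sd <- spec$noise_sd * 3
  v2 <- generate_subject_volume(65, spec2, seed = 3, wmh_multiplier = 20)
  expect_identical(v$labels, v2$labels)
})

test_that("default control cohort hits the published volumetry calibration", {
  spec <- phantom_spec()
  ages <- with_seed(100, pmin(pmax(rnorm(24, 37.0, 9.4), 18), 55))
  fr <- lapply(seq_along(ages), function(i)
    tissue_fractions(generate_subject_volume(ages[i], spec, seed = i)))
  csf <- vapply(fr, `[[`, 0, "csf_pct_icv")
  gm <- vapply(fr, `[[`, 0, "gm_pct_icv")
  wm <- vapply(fr, `[[`, 0, "wm_pct_icv")
  expect_lt(abs(mean(csf) - 10.80), 1.5) # published control mean 10.80 (2.13)
  expect_lt(abs(mean(gm) - 52.31), 1.5)  # published control mean 52.31 (2.64)
  expect_lt(abs(mean(wm) - 36.89), 1.5)  # published control mean 36.89 (1.45)
})

test_that("cohort manifests: roles, effective age identity, determinism", {
  spec <- tiny_phantom()
  co <- cohort_spec(n_training = 5, n_controls = 4, n_patients = 6,
                    seed = 42)
  res <- generate_cohort(co, spec)
  man <- res$manifest
  expect_equal(nrow(man), 15)
  expect_equal(man$effective_age,
               man$chronological_age + man$offset_delta)
  expect_true(all(man$offset_delta[man$role != "patient"] == 0))
  expect_true(all(man$offset_delta[man$role == "patient"] >= 0))
  expect_identical(man, generate_cohort(co, spec)$manifest)

  # no patients -> manifest has only training + control rows
  res0 <- generate_cohort(cohort_spec(n_training = 3, n_controls = 2,
                                      n_patients = 0, seed = 1),
                          spec, keep_volumes = FALSE)
  expect_setequal(unique(res0$manifest$role), c("training", "control"))
})

test_that("default patient ages match the reference cohort", {
  man <- generate_cohort(cohort_spec(seed = 7), tiny_phantom(),
                         keep_volumes = FALSE)$manifest
  pat <- man[man$role == "patient", ]
  expect_equal(nrow(pat), 70)
  expect_lt(abs(mean(pat$chronological_age) - 35.9), 2)
  expect_true(all(pat$chronological_age >= 18 &
                    pat$chronological_age <= 55))
  ctl <- man[man$role == "control", ]
  expect_lt(abs(mean(ctl$chronological_age) - 37.0), 4)
})

test_that("null offset makes patients indistinguishable from controls", {
  spec <- tiny_phantom()
  sig <- vapply(1:10, function(s) {
    res <- generate_cohort(cohort_spec(n_training = 0, n_controls = 12,
                                       n_patients = 12,
                                       offset_mean_sd = c(0, 0), seed = s),
                           spec)
    man <- res$manifest
    vf <- vapply(res$volumes, function(v)
      sum(v$labels == TISSUE_LABELS[["ventricle"]]) / sum(v$labels > 0), 0)
    two_sample_t(vf[man$role == "patient"],
                 vf[man$role == "control"])$p_value < 0.05
  }, logical(1))
  expect_lte(sum(sig), 2) # non-significant in >= 8/10 seeds
})

test_that("covariate model: exact values without noise, age slope with noise", {
  co <- cohort_spec()
  co$nfl_model$noise_sd <- 0
  co$cognition_model$sd <- 0
  rec <- sample_covariates(list(chronological_age = 36, offset_delta = 0),
                           co, seed = 1)
  for (d in cognitive_domains()) expect_equal(rec[[d]], 100)

  co$nfl_model$intercept <- 0.5
  co$nfl_model$slope_per_year_age <- 0.005
  co$nfl_model$slope_per_year_offset <- 0.02
  rec2 <- sample_covariates(list(chronological_age = 36, offset_delta = 4),
                            co, seed = 1)
  expect_equal(rec2$log_nfl, 0.5 + 0.26, tolerance = 1e-12)

  # over many controls the sampled log-NfL rises with age
  co2 <- cohort_spec(n_training = 0, n_controls = 500, n_patients = 0,
                     seed = 77)
  man <- generate_cohort(co2, tiny_phantom(), keep_volumes = FALSE)$manifest
  ct <- correlate(man$log_nfl, man$chronological_age)
  expect_gt(ct$r, 0)
  expect_lt(ct$p_value, 0.01)
})

test_that("cognitive scores fall with the aging offset and warn when extreme", {
  co <- cohort_spec()
  co$cognition_model$sd <- 0
  rec <- sample_covariates(list(chronological_age = 40, offset_delta = 8),
                           co, seed = 1)
  expect_equal(rec$reaction_time, 100 - 2.5 * 8)
  expect_warning(
    sample_covariates(list(chronological_age = 40, offset_delta = 30),
                      co, seed = 1),
    "outside")
})

test_that("manifest CSV round-trips with the documented header", {
  spec <- tiny_phantom()
  dir <- withr::local_tempdir()
  res <- generate_cohort(cohort_spec(n_training = 2, n_controls = 2,
                                     n_patients = 2, seed = 3),
                         spec, dir = dir, keep_volumes = FALSE)
  path <- file.path(dir, "manifest.csv")
  expect_true(file.exists(path))
  hdr <- names(read.csv(path, nrows = 1))
  expect_equal(hdr, c("id", "role", "chronological_age", "offset_delta",
                      "log_nfl", cognitive_domains(), "volume_path"))
  man2 <- read_manifest(path)
  expect_equal(man2$effective_age,
               man2$chronological_age + man2$offset_delta)
  # volumes landed on disk as NIfTI pairs
  expect_true(all(file.exists(res$manifest$volume_path)))
  v <- read_labeled_volume(res$manifest$volume_path[1])
  expect_s3_class(v, "labeled_volume")
})

test_that("YAML configuration mirrors the constructor fields", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("phantom:",
               "  noise_sd: 2.5",
               "cohort:",
               "  n_training: 12",
               "  n_patients: 3",
               "  offset_mean_sd: [2, 1]",
               "  seed: 99"), path)
  cfg <- read_spec_yaml(path)
  expect_s3_class(cfg$phantom, "phantom_spec")
  expect_equal(cfg$phantom$noise_sd, 2.5)
  expect_equal(cfg$phantom$grid_shape, c(32L, 32L, 32L)) # defaults kept
  expect_equal(cfg$cohort$n_training, 12L)
  expect_equal(cfg$cohort$offset_mean_sd, c(2, 1))
  expect_equal(cfg$cohort$seed, 99L)
})

test_that("configuration validation rejects impossible phantoms", {
  expect_error(phantom_spec(grid_shape = c(8, 32, 32)), ">= 16")
  expect_error(phantom_spec(ventricle_growth = 0), "ventricle_growth")
  expect_error(phantom_spec(brain_semiaxes = c(20, 15, 13)), "fit inside")
  expect_error(phantom_spec(ventricle_base_volume = 5000), "do not fit")
  expect_error(generate_subject_volume(90, phantom_spec()))
})
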