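# Volume I/O, min-max normalization, affine resampling, tissue volumetry.

test_that("min-max normalization: worked examples, idempotence, errors", {
  vol <- array(0, c(2, 2, 2))
  vol[1:3] <- c(2, 4, 6)
  mask <- array(FALSE, c(2, 2, 2)); mask[1:3] <- TRUE
  out <- minmax_normalize(vol, mask)
  expect_equal(out[1:3], c(0, 0.5, 1))
  expect_true(all(out[!mask] == 0))

  # already [0,1] with attained extremes: unchanged on the mask
  expect_equal(minmax_normalize(out, mask)[mask], out[mask])

  expect_error(minmax_normalize(array(5, c(2, 2, 2)), mask), "degenerate")
  expect_error(minmax_normalize(vol, array(FALSE, c(2, 2, 2))), "empty")
})

test_that("affine resampling: identity, integer shifts, inverse round-trip", {
  set.seed(14)
  vol <- array(rnorm(16^3), c(16, 16, 16))
  eye <- diag(4)
  expect_equal(resample_affine(vol, eye, dim(vol)), vol, tolerance = 1e-12)

  # pure +2 voxel shift along x, nearest: voxel-exact copy
  A <- diag(4); A[1, 4] <- -2 # target (i) samples source (i - 2)... inverse map
  shifted <- resample_affine(vol, A, dim(vol), "nearest")
  expect_equal(shifted[3:16, , ], vol[1:14, , ])
  expect_true(all(shifted[1:2, , ] == 0))

  # small random affine round-trip recovers interior voxels
  theta <- 0.07
  R <- diag(4)
  R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  R[1:3, 4] <- c(0.4, -0.3, 0.2)
  smooth <- array(0, c(16, 16, 16)) # smooth field: trilinear error ~ h^2
  for (i in 1:16) for (j in 1:16) for (k in 1:16)
    smooth[i, j, k] <- sin(i / 5) * cos(j / 6) + k / 16
  fwd <- resample_affine(smooth, R, dim(smooth))
  back <- resample_affine(fwd, solve(R), dim(smooth))
  core <- 5:12
  rng <- diff(range(smooth))
  err <- abs(back[core, core, core] - smooth[core, core, core]) / rng
  expect_lt(max(err), 1e-2)
  expect_lt(mean(err), 1e-3)

  expect_error(resample_affine(vol, matrix(0, 4, 4), dim(vol)), "singular")
})

test_that("tissue fractions: counting oracle, WMH in mL, invariances", {
  # 1000-voxel brain: 520 GM, 370 WM, 110 CSF(+ventricle), in a 10^3 grid
  labels <- array(0L, c(10, 10, 10))
  labels[1:520] <- 2L
  labels[521:890] <- 3L
  labels[891:950] <- 1L
  labels[951:1000] <- 4L
  vol <- labeled_volume(array(0, c(10, 10, 10)), labels, c(1, 1, 1))
  fr <- tissue_fractions(vol)
  expect_equal(fr$gm_pct_icv, 52)
  expect_equal(fr$wm_pct_icv, 37)
  expect_equal(fr$csf_pct_icv, 11)
  expect_equal(fr$wmh_ml, 0)
  expect_equal(fr$gm_pct_icv + fr$wm_pct_icv + fr$csf_pct_icv, 100)

  # single WMH voxel of 1 mm^3 -> 0.001 mL; counted inside WM for the %
  labels2 <- labels
  labels2[600] <- 5L
  fr2 <- tissue_fractions(labeled_volume(array(0, c(10, 10, 10)), labels2,
                                         c(1, 1, 1)))
  expect_equal(fr2$wmh_ml, 0.001)
  expect_equal(fr2$wm_pct_icv, 37)

  # voxel-order permutation leaves all fractions unchanged
  perm <- sample(1000)
  labels3 <- array(labels[perm], c(10, 10, 10))
  fr3 <- tissue_fractions(labeled_volume(array(0, c(10, 10, 10)), labels3,
                                         c(1, 1, 1)))
  expect_equal(unclass(fr3), unclass(fr))

  expect_error(tissue_fractions(labeled_volume(array(0, c(4, 4, 4)),
                                               array(0L, c(4, 4, 4)),
                                               c(1, 1, 1))), "empty")
})

test_that("voxelized phantom fractions match the label-count ground truth", {
  spec <- phantom_spec()
  v <- generate_subject_volume(50, spec, seed = 6)
  fr <- tissue_fractions(v)
  counts <- table(factor(v$labels, levels = 0:5))
  icv <- sum(counts[-1])
  expect_equal(fr$gm_pct_icv, 100 * counts[["2"]] / icv)
  expect_equal(fr$csf_pct_icv, 100 * (counts[["1"]] + counts[["4"]]) / icv)
  expect_equal(fr$wmh_ml, counts[["5"]] * prod(spec$voxel_size) / 1000)
})

test_that("NIfTI pairs round-trip intensities, labels and voxel size", {
  spec <- tiny_phantom()
  v <- generate_subject_volume(40, spec, seed = 8)
  path <- file.path(withr::local_tempdir(), "subj_t1.nii.gz")
  write_labeled_volume(v, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("_t1", "_labels", path)))
  v2 <- read_labeled_volume(path)
  expect_equal(v2$intensities, v$intensities, tolerance = 1e-6)
  expect_identical(v2$labels, v$labels)
  expect_equal(v2$voxel_size, v$voxel_size)
})

test_that("volumetry table writes one row per subject", {
  spec <- tiny_phantom()
  vols <- list(s1 = generate_subject_volume(30, spec, seed = 1),
               s2 = generate_subject_volume(60, spec, seed = 2))
  path <- tempfile(fileext = ".csv")
  tab <- volumetry_table(vols, path)
  expect_equal(tab$id, c("s1", "s2"))
  expect_gt(tab$csf_pct[2], tab$csf_pct[1]) # older phantom, more CSF
  expect_equal(names(read.csv(path)),
               c("id", "gm_pct", "wm_pct", "csf_pct", "wmh_ml"))
})
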