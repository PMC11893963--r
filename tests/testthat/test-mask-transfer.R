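test_that("identity resampling is bit-identical and off-grid masks come back empty", {
  g <- affine_geometry(c(2, 3, 4), c(1, 1, 1), diag(3), c(6, 5, 4))
  m <- array(FALSE, g$dim); m[2:4, 2:3, 2:3] <- TRUE
  om <- organ_mask("LIVER", m, g)
  expect_identical(resample_mask(om, g)$mask, m)

  far <- affine_geometry(c(2, 3, 4), c(500, 500, 500), diag(3), c(6, 5, 4))
  expect_message(res <- resample_mask(om, far), "empty after resampling")
  expect_false(any(res$mask))
})

test_that("cube resampling onto a coarse grid matches the voxel-centre loop oracle", {
  src <- affine_geometry(c(1, 1, 1), c(0.5, 0.5, 0.5), diag(3), c(40, 40, 40))
  m <- array(FALSE, src$dim); m[11:30, 11:30, 11:30] <- TRUE  # 20 mm cube
  om <- organ_mask("LUNG_LEFT", m, src)
  tgt <- affine_geometry(c(4.8, 4.8, 4.8), c(2.4, 2.4, 2.4), diag(3), c(10, 10, 10))
  res <- resample_mask(om, tgt)
  expect_identical(res$mask, resample_oracle(om, tgt))
  # volume within one target-voxel shell of the 8 cm^3 truth
  vol <- mask_volume(res)
  shell <- 6 * 2^2 * 0.48  # cube surface area (cm^2) x one voxel (cm)
  expect_lt(abs(vol - 8), shell)
})

test_that("resampling equals the loop oracle on random rotated geometries", {
  set.seed(99)
  for (rep in 1:5) {
    src <- random_geometry(dim = c(6, 6, 6))
    m <- array(runif(prod(src$dim)) < 0.3, src$dim)
    if (!any(m)) m[1] <- TRUE
    om <- organ_mask("LIVER", m, src)
    tgt <- random_geometry(dim = c(7, 5, 6))
    tgt$origin <- src$origin + runif(3, -3, 3)
    tgt <- affine_geometry(tgt$spacing, tgt$origin, tgt$orientation, tgt$dim)
    expect_identical(resample_mask(om, tgt)$mask, resample_oracle(om, tgt))
  }
})

test_that("metric dilation matches offset enumeration and is extensive/monotone", {
  g <- affine_geometry(c(2, 2, 2), dim = c(7, 7, 7))
  one <- array(FALSE, g$dim); one[4, 4, 4] <- TRUE
  d <- lungshunt:::dilate_mm(one, c(2, 2, 2), g$spacing)
  # 2 mm radius on a 2 mm grid reaches exactly the 6-connected cross
  expect_equal(sum(d), 7)
  expect_true(d[4, 4, 4] && d[3, 4, 4] && d[5, 4, 4] && d[4, 3, 4] &&
                d[4, 5, 4] && d[4, 4, 3] && d[4, 4, 5])

  set.seed(5)
  for (rep in 1:5) {
    m <- array(runif(7^3) < 0.1, c(7, 7, 7))
    sp <- runif(3, 1, 4)
    r1 <- runif(1, 0, 5); r2 <- r1 + runif(1, 0, 4)
    d1 <- lungshunt:::dilate_mm(m, rep(r1, 3), sp)
    d2 <- lungshunt:::dilate_mm(m, rep(r2, 3), sp)
    expect_true(all(d1[m]))          # extensive
    expect_true(all(d2[d1]))         # monotone in radius
    expect_identical(d1, dilate_oracle(m, rep(r1, 3), sp))
  }
})

test_that("augmentation honours the precedence order and never loses original voxels", {
  # liver and lung cubes one voxel apart, one-voxel margins: the contested
  # gap voxels must go to the lung
  g <- affine_geometry(c(2, 2, 2), dim = c(10, 6, 6))
  lv <- array(FALSE, g$dim); lv[2:4, 2:5, 2:5] <- TRUE
  lu <- array(FALSE, g$dim); lu[6:8, 2:5, 2:5] <- TRUE
  lr <- array(FALSE, g$dim); lr[10, 6, 6] <- TRUE
  masks <- list(liver = organ_mask("LIVER", lv, g),
                lung_left = organ_mask("LUNG_LEFT", lu, g),
                lung_right = organ_mask("LUNG_RIGHT", lr, g))
  p <- augmentation_params(liver_radius_mm = 2, lung_radius_mm = 2,
                           extra_cranio_caudal_mm = 0)
  vs <- augment_vois(masks$liver, masks$lung_left, masks$lung_right, p)
  expect_true(all(vs$lung_left$mask[5, 2:5, 2:5]))   # gap claimed by lung
  expect_false(any(vs$liver$mask[5, 2:5, 2:5]))
  oracle <- augment_oracle(masks$liver, masks$lung_left, masks$lung_right, p)
  expect_identical(vs$liver$mask, oracle$liver)
  expect_identical(vs$lung_left$mask, oracle$lung_left)
  expect_identical(vs$lung_right$mask, oracle$lung_right)

  # zero radii: exact identity
  vs0 <- augment_vois(masks$liver, masks$lung_left, masks$lung_right,
                      augmentation_params(0, 0, 0))
  expect_identical(vs0$liver$mask, lv)
  expect_identical(vs0$lung_left$mask, lu)
  expect_false(any(vs0$provenance$liver))

  # overlapping inputs are an upstream bug
  bad <- organ_mask("LIVER", lu, g)
  expect_error(augment_vois(bad, masks$lung_left, masks$lung_right, p),
               "overlap")
})

test_that("single liver voxel with 2 mm radius becomes the 7-voxel cross", {
  g <- affine_geometry(c(2, 2, 2), dim = c(5, 5, 5))
  lv <- array(FALSE, g$dim); lv[3, 3, 3] <- TRUE
  ll <- array(FALSE, g$dim); ll[1, 1, 1] <- TRUE
  lr <- array(FALSE, g$dim); lr[5, 5, 5] <- TRUE
  vs <- augment_vois(organ_mask("LIVER", lv, g), organ_mask("LUNG_LEFT", ll, g),
                     organ_mask("LUNG_RIGHT", lr, g),
                     augmentation_params(2, 0, 0))
  expect_equal(sum(vs$liver$mask), 7)
})

test_that("mask volume follows voxel counting and the closed-form ellipsoid check", {
  g <- affine_geometry(c(1, 1, 1), dim = c(10, 10, 10))
  m <- array(FALSE, g$dim); m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(mask_volume(m, geometry = g), 1.0)
  expect_equal(mask_volume(array(FALSE, g$dim), geometry = g), 0)

  ge <- affine_geometry(c(1, 1, 1), c(0.5, 0.5, 0.5), diag(3), c(130, 110, 90))
  me <- lungshunt:::rasterize_ellipsoid(ge, c(65, 55, 45), c(60, 50, 40))
  truth <- 4 / 3 * pi * 60 * 50 * 40 / 1000
  expect_lt(abs(mask_volume(me, geometry = ge) - truth) / truth, 0.01)
})

test_that("crop correction imputes counts only when the lung touches the superior face", {
  g <- affine_geometry(c(4, 4, 4), c(2, 2, 2), diag(3), c(16, 16, 20))
  lung <- array(FALSE, g$dim); lung[4:12, 4:12, 8:16] <- TRUE
  liver <- array(FALSE, g$dim); liver[4:12, 4:12, 2:5] <- TRUE
  lr <- array(FALSE, g$dim); lr[14, 14, 10] <- TRUE
  counts <- array(0, g$dim); counts[lung] <- 3; counts[liver] <- 10
  spect <- image_volume(counts, g$spacing, g$origin, modality = "SPECT_AC")
  vs <- augment_vois(organ_mask("LIVER", liver, g),
                     organ_mask("LUNG_LEFT", lung, g),
                     organ_mask("LUNG_RIGHT", lr, g),
                     augmentation_params(0, 0, 0))
  # not touching the top face: no correction, warn when reference >> imaged
  expect_message(vs1 <- correct_cropped_lung(vs, spect, 2 * mask_volume(vs$lung_left)),
                 "does not touch the superior face")
  expect_null(vs1$crop_correction)

  # crop above slice 14: the lung apex is cut; imputed counts restore the total
  spect_c <- crop_superior(spect, 14)
  crop <- function(m) crop_superior(m, 14)
  vs_c <- augment_vois(crop(vs$liver), crop(vs$lung_left), crop(vs$lung_right),
                       augmentation_params(0, 0, 0))
  ref <- mask_volume(vs$lung_left) + mask_volume(vs$lung_right)
  vs_c <- correct_cropped_lung(vs_c, spect_c, ref)
  expect_false(is.null(vs_c$crop_correction))
  cs <- organ_counts(spect_c, vs_c)
  full <- sum(counts[lung | lr])
  expect_lt(abs(cs$total_lung_count - full) / full, 0.02)
  expect_equal(cs$total_lung_count,
               cs$lung_left_count + cs$lung_right_count + cs$crop_added_counts)

  # touching face but nothing missing: zero imputed counts
  vs2 <- correct_cropped_lung(vs_c, spect_c,
                              mask_volume(vs_c$lung_left) + mask_volume(vs_c$lung_right))
  expect_equal(vs2$crop_correction$added_counts, 0)
  expect_error(correct_cropped_lung(vs_c, spect_c, 1), "smaller than the imaged")
})
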