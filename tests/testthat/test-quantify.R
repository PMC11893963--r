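make_voiset <- function(g, liver, lung_left, lung_right) {
  augment_vois(organ_mask("LIVER", liver, g),
               organ_mask("LUNG_LEFT", lung_left, g),
               organ_mask("LUNG_RIGHT", lung_right, g),
               augmentation_params(0, 0, 0))
}

test_that("organ counts are per-voxel sums, additive, and match a loop oracle", {
  g <- affine_geometry(c(2, 2, 2), dim = c(8, 8, 8))
  lv <- array(FALSE, g$dim); lv[1:2, 1:2, 1:2] <- TRUE
  ll <- array(FALSE, g$dim); ll[5:6, 5:6, 5:6] <- TRUE
  lr <- array(FALSE, g$dim); lr[8, 8, 8] <- TRUE
  vs <- make_voiset(g, lv, ll, lr)
  uni <- image_volume(array(2, g$dim), g$spacing, modality = "SPECT_AC")
  cs <- organ_counts(uni, vs)
  expect_equal(cs$total_liver_count, 16)
  expect_equal(cs$total_lung_count, cs$lung_left_count + cs$lung_right_count)

  set.seed(21)
  pois <- image_volume(array(as.double(rpois(8^3, 20)), rep(8, 3)), g$spacing,
                       modality = "SPECT_AC")
  cs2 <- organ_counts(pois, vs)
  brute <- function(m) {
    s <- 0
    for (k in 1:8) for (j in 1:8) for (i in 1:8) {
      if (m[i, j, k]) s <- s + pois$voxels[i, j, k]
    }
    s
  }
  expect_equal(cs2$lung_left_count, brute(ll))
  expect_equal(cs2$total_liver_count, brute(lv))
  expect_equal(cs2$total_lung_count, brute(ll) + brute(lr))
  # additivity over disjoint masks
  expect_equal(brute(ll | lr | lv), cs2$total_lung_count + cs2$total_liver_count)

  wrong <- image_volume(array(1, c(4, 4, 4)), c(4, 4, 4), modality = "SPECT_AC")
  expect_error(organ_counts(wrong, vs), "different grids")
})

test_that("3D SPECT LSF reproduces the count-ratio formula and its boundaries", {
  expect_equal(round(lsf_3d(list(total_lung_count = 1793391.25,
                                 total_liver_count = 13326405))$lsf_percent, 2),
               11.86)
  expect_equal(lsf_3d(list(total_lung_count = 0,
                           total_liver_count = 10))$lsf_percent, 0)
  expect_equal(lsf_3d(list(total_lung_count = 5,
                           total_liver_count = 5))$lsf_percent, 50)
  expect_error(lsf_3d(list(total_lung_count = 0, total_liver_count = 0)),
               "undefined")
})

test_that("planar organ counts mirror the posterior view exactly once", {
  n <- 8
  ant <- matrix(0, n, n); ant[2, 4] <- 100          # source on patient right
  post <- matrix(0, n, n); post[n - 1, 4] <- 400    # same source, camera-mirrored
  rois <- list(liver = matrix(FALSE, n, n), lung = matrix(FALSE, n, n))
  rois$lung[2, 4] <- TRUE
  rois$liver[5, 5] <- TRUE; ant[5, 5] <- 10; post[4, 5] <- 10
  pc <- planar_organ_counts(planar_image(ant, 4, "ANTERIOR"),
                            planar_image(post, 4, "POSTERIOR"), rois)
  expect_equal(pc$geomean_lung_count, sqrt(100 * 400))  # = 200
  expect_equal(pc$ant_lung_count, 100)
  expect_equal(pc$post_lung_count, 400)

  # identical views: geomean equals the single-view total
  pc2 <- planar_organ_counts(planar_image(ant, 4, "ANTERIOR"),
                             planar_image(ant[rev(seq_len(n)), ], 4, "POSTERIOR"),
                             rois)
  expect_equal(pc2$geomean_lung_count, 100)

  # zero posterior total: geomean 0 with a warning
  post0 <- matrix(0, n, n); post0[4, 5] <- 1
  expect_message(pc3 <- planar_organ_counts(planar_image(ant, 4, "ANTERIOR"),
                                            planar_image(post0, 4, "POSTERIOR"),
                                            rois),
                 "zero organ total")
  expect_equal(pc3$geomean_lung_count, 0)

  expect_error(planar_organ_counts(planar_image(ant, 4, "ANTERIOR"),
                                   planar_image(matrix(0, 4, 4), 4, "POSTERIOR"),
                                   rois),
               "mismatch")
})

test_that("planar LSF reproduces the geometric-mean formula", {
  expect_equal(round(lsf_planar(list(geomean_lung_count = 212709.6,
                                     geomean_liver_count = 712039.1))$lsf_percent, 2),
               23.00)
  expect_equal(round(lsf_planar(list(geomean_lung_count = 327558.4,
                                     geomean_liver_count = 875329.1))$lsf_percent, 1),
               27.2)
  expect_equal(lsf_planar(list(geomean_lung_count = 3,
                               geomean_liver_count = 3))$lsf_percent, 50)
  expect_error(lsf_planar(list(geomean_lung_count = 0,
                               geomean_liver_count = 0)), "undefined")
})

test_that("ground-truth LSF handles residuals, decay and degenerate cases", {
  a <- ground_truth_activities(RLA = 5, LLA = 5, LA = 90, rlr = 1, llr = 1,
                               lr = 10)
  expect_equal(lsf_ground_truth(a)$lsf_percent, 8 / 88 * 100, tolerance = 1e-12)

  # zero residuals and equal assay times reduce to the 3D count-ratio form
  b <- ground_truth_activities(RLA = 2, LLA = 1, LA = 27)
  expect_equal(lsf_ground_truth(b)$lsf_percent,
               lsf_3d(list(total_lung_count = 3,
                           total_liver_count = 27))$lsf_percent)

  # decay correction: one half-life halves every activity, leaving the ratio
  d <- ground_truth_activities(RLA = 2, LLA = 1, LA = 27, assay_time = 0,
                               reference_time = 6.0067)
  expect_equal(lsf_ground_truth(d)$lsf_percent,
               lsf_ground_truth(b)$lsf_percent, tolerance = 1e-12)
  expect_equal(lsf_ground_truth(d)$inputs$net_liver_MBq, 13.5, tolerance = 1e-9)

  z <- ground_truth_activities(RLA = 0, LLA = 0, LA = 10)
  expect_equal(lsf_ground_truth(z)$lsf_percent, 0)
  expect_error(ground_truth_activities(RLA = 1, LLA = 1, LA = 1, rlr = 2),
               "residual exceeds")
})

test_that("percentage difference and accuracy follow their signed formulas", {
  expect_equal(percentage_difference(10, 10), 0)
  expect_equal(percentage_difference(6, 3), 100)
  expect_equal(percentage_difference(23.00, 11.86), (23 - 11.86) / 11.86 * 100)
  expect_error(percentage_difference(5, 0), "undefined")

  expect_equal(accuracy_vs_truth(13.5, 13.5), 0)
  expect_equal(accuracy_vs_truth(27, 13.5), 100)
  expect_equal(accuracy_vs_truth(11.86, 13.5), (11.86 - 13.5) / 13.5 * 100)
  expect_error(accuracy_vs_truth(5, 0), "undefined|zero")
})

test_that("quartiles use the (n+1)/4 rank rule with interpolation and clipping", {
  q <- quartile_summary(1:7)
  expect_equal(c(q$q1, q$q3, q$iqr), c(2, 6, 4))
  expect_equal(quartile_summary(rep(4.2, 10))$iqr, 0)
  # fractional ranks agree with the (n+1)p definition (quantile type 6)
  set.seed(8)
  for (rep in 1:10) {
    x <- runif(sample(4:40, 1), 0, 30)
    q <- quartile_summary(x)
    ref <- unname(stats::quantile(x, c(0.25, 0.75), type = 6))
    expect_equal(c(q$q1, q$q3), ref, tolerance = 1e-12)
  }
  # rank clipping at tiny n
  q2 <- quartile_summary(c(3, 9))
  expect_equal(q2$q1, 3)   # rank 0.75 clips to 1
  expect_equal(q2$q3, 9)   # rank 2.25 clips to 2
  expect_error(quartile_summary(numeric(0)), "at least one")
})

test_that("every LSF is invariant under count rescaling and monotone in its counts", {
  set.seed(13)
  for (rep in 1:25) {
    lung <- runif(1, 0, 1e6); liver <- runif(1, 1, 1e7); c0 <- runif(1, 1e-3, 1e3)
    l1 <- lsf_3d(list(total_lung_count = lung, total_liver_count = liver))
    l2 <- lsf_3d(list(total_lung_count = c0 * lung, total_liver_count = c0 * liver))
    expect_equal(l1$lsf_percent, l2$lsf_percent, tolerance = 1e-10)
    p1 <- lsf_planar(list(geomean_lung_count = lung, geomean_liver_count = liver))
    p2 <- lsf_planar(list(geomean_lung_count = c0 * lung,
                          geomean_liver_count = c0 * liver))
    expect_equal(p1$lsf_percent, p2$lsf_percent, tolerance = 1e-10)
    # strictly increasing in lung counts, decreasing in liver counts
    up <- lsf_3d(list(total_lung_count = lung + 1, total_liver_count = liver))
    dn <- lsf_3d(list(total_lung_count = lung, total_liver_count = liver + 1))
    expect_gt(up$lsf_percent, l1$lsf_percent)
    expect_lt(dn$lsf_percent, l1$lsf_percent)
  }
})

test_that("geometric means stay within the anterior/posterior bounds", {
  set.seed(17)
  n <- 10
  for (rep in 1:25) {
    ant <- matrix(runif(n * n, 0, 50), n, n)
    post <- matrix(runif(n * n, 0, 50), n, n)
    roi <- matrix(runif(n * n) < 0.4, n, n)
    rois <- list(liver = roi, lung = matrix(runif(n * n) < 0.3, n, n))
    pc <- planar_organ_counts(planar_image(ant, 4, "ANTERIOR"),
                              planar_image(post, 4, "POSTERIOR"), rois)
    for (org in c("lung", "liver")) {
      gm <- pc[[paste0("geomean_", org, "_count")]]
      lo <- min(pc[[paste0("ant_", org, "_count")]],
                pc[[paste0("post_", org, "_count")]])
      hi <- max(pc[[paste0("ant_", org, "_count")]],
                pc[[paste0("post_", org, "_count")]])
      expect_gte(gm, lo); expect_lte(gm, hi)
    }
  }
})

test_that("cohort summaries report per-case PD and both average readings", {
  df <- data.frame(case_id = 1:4,
                   planar_lsf_percent = c(8, 6, 10, 4),
                   spect_lsf_percent = c(4, 3, 5, 2))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  s <- cohort_summary(f)
  expect_equal(s$cases$pd_percent, rep(100, 4))
  expect_equal(s$mean_pd_percent, 100)
  expect_equal(s$pd_of_means_percent, 100)
  expect_equal(s$planar$iqr, s$planar$q3 - s$planar$q1)
  expect_error(cohort_summary(data.frame(x = 1)), "columns")
})
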