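test_that("enhanced area is the labelled-voxel percentage", {
  labels <- matrix(0L, 25, 25)
  labels[1:20, 1:25] <- 1L            # 500 myocardial voxels
  labels[1:5, 1:5] <- 2L              # 25 enhanced
  myo <- labels >= 1L
  rois <- roi_set(myo, myo & FALSE, lv_center = c(13, 13), labels = labels)
  rep <- enhanced_area(rois, "LGE")
  expect_equal(rep$enhanced_area_pct, 5)
  expect_equal(rep$n_enhanced, 25)
  expect_equal(rep$n_myocardium, 500)
  labels[labels == 2L] <- 1L
  rois0 <- roi_set(myo, myo & FALSE, lv_center = c(13, 13), labels = labels)
  expect_equal(enhanced_area(rois0)$enhanced_area_pct, 0)
  empty <- roi_set(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2),
                   lv_center = c(1, 1))
  empty$labels[] <- 0L
  expect_error(enhanced_area(empty), "no labelled")
})

test_that("transmurality follows the central ray through the lesion", {
  # full-thickness wedge: every myocardial ray sample is enhanced
  ds_full <- noise_free_phantom(1)
  rois <- classify_delta_s(
    parametric_map(ifelse(ds_full$truth$enhanced_mask, 300, 100)),
    ds_full$rois, threshold_spec(197))
  t_full <- transmurality(rois)
  expect_equal(as.numeric(t_full), 100)
  ang <- attr(t_full, "center_angle_deg")
  expect_equal(ang, 60, tolerance = 3)  # lesion spans 30-90 deg

  # half-thickness lesion: about 50 %
  ds_half <- noise_free_phantom(0.5)
  rois_h <- classify_delta_s(
    parametric_map(ifelse(ds_half$truth$enhanced_mask, 300, 100)),
    ds_half$rois, threshold_spec(197))
  expect_equal(as.numeric(transmurality(rois_h)), 50, tolerance = 5)

  # no enhancement: undefined, not zero
  rois_none <- classify_delta_s(parametric_map(matrix(100, 8, 8)),
                                make_rois(8), threshold_spec(197))
  expect_error(transmurality(rois_none), class = "bssfp2pt_no_enhancement")
})

test_that("single mid-wall voxel transmurality matches brute-force ray marching", {
  ds <- noise_free_phantom(1)
  labels <- matrix(0L, 128, 128)
  labels[ds$rois$myocardium] <- 1L
  # one enhanced voxel on the +x axis, mid-wall (radius 25)
  ctr <- ds$rois$lv_center
  vox <- c(round(ctr[1]), round(ctr[2] + 25))
  labels[vox[1], vox[2]] <- 2L
  rois <- roi_set(ds$rois$myocardium, ds$rois$remote_roi,
                  lv_center = ctr, labels = labels)
  got <- as.numeric(transmurality(rois))
  # independent ray march at fine step along the voxel's angle
  ang <- atan2(ctr[1] - vox[1], vox[2] - ctr[2])
  r <- seq(0, 90, by = 0.25)
  rows <- round(ctr[1] - r * sin(ang)); cols <- round(ctr[2] + r * cos(ang))
  ok <- rows >= 1 & rows <= 128 & cols >= 1 & cols <= 128
  lab <- labels[cbind(rows[ok], cols[ok])]
  expect_equal(got, 100 * sum(lab == 2L) / sum(lab >= 1L), tolerance = 1e-9)
  expect_lt(got, 25)  # a single voxel's radial footprint is small
})

test_that("gpc_map reproduces the worked scalar example and identities", {
  m <- matrix(1000, 2, 2); p <- matrix(500, 2, 2)
  myo <- matrix(TRUE, 2, 2)
  g <- gpc_map(m, p, 1600, 400, myo)
  expect_equal(g$values[1, 1], 0.001 / 0.001875, tolerance = 1e-12)
  expect_equal(round(g$values[1, 1], 3), 0.533)
  # myocardial delta-R1 equal to blood delta-R1 -> GPC 1
  g1 <- gpc_map(matrix(1600, 1, 1), matrix(400, 1, 1), 1600, 400,
                matrix(TRUE, 1, 1))
  expect_equal(g1$values[1, 1], 1)
  # invariant under a global time-unit rescaling (ms -> s)
  g_s <- gpc_map(m / 1000, p / 1000, 1.6, 0.4, myo)
  expect_equal(g_s$values, g$values, tolerance = 1e-12)
  # blood delta-R1 <= 0 is an input error
  expect_error(gpc_map(m, p, 400, 1600, myo), "blood delta-R1")
  # non-positive myocardial delta-R1 voxels are invalidated, not computed
  p2 <- p; p2[1, 1] <- 1200
  g2 <- gpc_map(m, p2, 1600, 400, myo)
  expect_false(g2$valid_mask[1, 1])
})

test_that("phantom GPC recovery is within 1 % at zero T1 noise", {
  ds <- noise_free_phantom()
  bt1 <- blood_t1_scalars(ds$t1_pre, ds$t1_post, ds$rois$blood_roi)
  g <- gpc_map(ds$t1_pre, ds$t1_post, bt1[["pre"]], bt1[["post"]],
               ds$rois$myocardium)
  lesion <- ds$truth$enhanced_mask
  remote_med <- median(g$values[ds$rois$myocardium & !lesion])
  lesion_med <- median(g$values[lesion])
  expect_equal(remote_med, ds$truth$gpc[["remote"]], tolerance = 0.01)
  expect_equal(lesion_med, ds$truth$gpc[["lesion"]], tolerance = 0.01)
})

test_that("dice coefficient handles identity, disjoint and partial overlap", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, b), 0)
  c4 <- matrix(FALSE, 4, 4); c4[1:2, 2:3] <- TRUE  # |A|=|B|=4, overlap 2
  expect_equal(dice_coefficient(a, c4), 0.5)
  # symmetry
  expect_equal(dice_coefficient(a, c4), dice_coefficient(c4, a))
  # both empty: defined as 1 and flagged
  e <- matrix(FALSE, 2, 2)
  d <- dice_coefficient(e, e)
  expect_equal(as.numeric(d), 1)
  expect_true(attr(d, "both_empty"))
  expect_error(dice_coefficient(a, matrix(FALSE, 2, 2)), "shape")
})

test_that("area and transmurality are invariant under joint translation", {
  spec1 <- phantom_spec(noise_sigma = 0, center = c(60, 60),
                        lesion_transmurality = 0.5, seed = 4)
  spec2 <- phantom_spec(noise_sigma = 0, center = c(68, 66),
                        lesion_transmurality = 0.5, seed = 4)
  res <- lapply(list(spec1, spec2), function(sp) {
    ds <- generate_phantom(sp)
    rois <- classify_delta_s(
      parametric_map(ifelse(ds$truth$enhanced_mask, 300, 100)),
      ds$rois, threshold_spec(197))
    c(area = enhanced_area(rois)$enhanced_area_pct,
      trans = as.numeric(transmurality(rois)))
  })
  expect_equal(res[[1]][["area"]], res[[2]][["area"]], tolerance = 0.5)
  expect_equal(res[[1]][["trans"]], res[[2]][["trans"]], tolerance = 3)
})
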