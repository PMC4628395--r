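test_that("roi_set enforces the subset and label invariants", {
  myo <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  bad_remote <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)
  expect_error(roi_set(myo, bad_remote, lv_center = c(1, 1)), "subset")
  bad_labels <- matrix(c(0L, 2L, 0L, 0L), 2, 2)
  expect_error(roi_set(myo, myo & FALSE, lv_center = c(1, 1),
                       labels = bad_labels), "outside")
})

test_that("the n-SD rule reproduces hand-computed thresholds strictly", {
  # remote mean 100, SD 10 -> threshold 150; 151 enhanced, 150 not
  img <- matrix(100, 4, 4)
  img[1, 1:2] <- c(90, 110)      # remote voxels: mean 100, sd 10
  remote <- matrix(FALSE, 4, 4); remote[1, 1:2] <- TRUE
  img[1, 2] <- 110; img[1, 1] <- 90
  img[3, 3] <- 151; img[4, 4] <- 150
  rois <- roi_set(matrix(TRUE, 4, 4), remote, lv_center = c(2.5, 2.5))
  # sd of c(90,110) is 14.14; construct a 3-voxel ROI with sd exactly 10
  remote3 <- matrix(FALSE, 4, 4); remote3[1, 1:3] <- TRUE
  img[1, 1:3] <- c(90, 100, 110)  # mean 100, sample sd 10
  rois <- roi_set(matrix(TRUE, 4, 4), remote3, lv_center = c(2.5, 2.5))
  out <- classify_lge(img, rois, n_sd = 5)
  expect_equal(out$threshold$value, 150)
  expect_equal(out$labels[3, 3], 2L)
  expect_equal(out$labels[4, 4], 1L)  # strictly greater than
})

test_that("a constant remote ROI gives a zero-SD threshold at the mean", {
  img <- matrix(100, 3, 3); img[3, 3] <- 100.001
  remote <- matrix(FALSE, 3, 3); remote[1, ] <- TRUE
  rois <- roi_set(matrix(TRUE, 3, 3), remote, lv_center = c(2, 2))
  out <- classify_lge(img, rois, n_sd = 5)
  expect_equal(out$threshold$value, 100)
  expect_equal(sum(out$labels == 2L), 1)
  one_voxel <- matrix(FALSE, 3, 3); one_voxel[1, 1] <- TRUE
  rois1 <- roi_set(matrix(TRUE, 3, 3), one_voxel, lv_center = c(2, 2))
  expect_error(classify_lge(img, rois1, 5), "2 valid voxels")
})

test_that("control-cohort threshold is mean + 3 sample SD of subject means", {
  thr <- derive_delta_s_threshold(c(100, 110, 120, 130, 140))
  expect_equal(thr$value, 120 + 3 * sd(c(100, 110, 120, 130, 140)))
  expect_equal(thr$value, 167.4342, tolerance = 1e-4)
  expect_identical(thr$rule, "mean+3SD controls")
  # identical subjects: zero SD, threshold at the common mean
  expect_equal(derive_delta_s_threshold(c(115, 115, 115))$value, 115)
  expect_error(derive_delta_s_threshold(115), ">= 2")
  # absent cohort: the fixed clinical default applies
  expect_equal(fixed_delta_s_threshold()$value, 197)
  expect_identical(fixed_delta_s_threshold()$rule, "fixed")
})

test_that("delta-S classification is strict, masked and monotone in threshold", {
  vals <- matrix(100, 6, 6)
  vals[2, 2] <- 197; vals[2, 3] <- 197.0001; vals[5, 5] <- 300
  vals[4, 4] <- NA
  m <- parametric_map(vals)
  rois <- make_rois(6)
  out <- classify_delta_s(m, rois, fixed_delta_s_threshold())
  expect_equal(out$labels[2, 2], 1L)   # exactly at threshold: not enhanced
  expect_equal(out$labels[2, 3], 2L)
  expect_equal(out$labels[4, 4], 0L)   # invalid voxel excluded entirely
  expect_equal(sum(out$labels == 2L), 2)
  # uniform map below threshold: nothing enhances
  uni <- classify_delta_s(parametric_map(matrix(100, 6, 6)), rois,
                          fixed_delta_s_threshold())
  expect_equal(sum(uni$labels == 2L), 0)
  # raising the threshold never adds enhanced voxels
  n_enh <- vapply(c(50, 100, 150, 200, 250, 350), function(t)
    sum(classify_delta_s(m, rois, threshold_spec(t))$labels == 2L),
    numeric(1))
  expect_true(all(diff(n_enh) <= 0))
  # enhanced labels are always within the myocardium
  expect_false(any(out$labels == 2L & !rois$myocardium))
  all_na <- parametric_map(matrix(NA_real_, 6, 6))
  expect_error(classify_delta_s(all_na, rois), "valid")
})

test_that("border erosion thins an annulus by one voxel per side", {
  ds <- noise_free_phantom()
  rois <- ds$rois
  er <- erode_borders(rois, 1)
  expect_true(all(er$myocardium <= rois$myocardium))
  # radial thickness 10 becomes 8 along the cardinal directions
  pol_row <- ds$spec$center[1]
  row_prof <- er$myocardium[round(pol_row), ]
  runs <- rle(row_prof)
  expect_true(all(runs$lengths[runs$values] == 8))
  orig_runs <- rle(rois$myocardium[round(pol_row), ])
  expect_true(all(orig_runs$lengths[orig_runs$values] == 10))
  # n = 0 is the identity
  expect_identical(erode_borders(rois, 0), rois)
  # a full-image mask loses exactly its one-voxel border ring
  full <- roi_set(matrix(TRUE, 10, 10), matrix(FALSE, 10, 10),
                  lv_center = c(5, 5))
  ef <- erode_borders(full, 1)
  expect_equal(sum(ef$myocardium), 8 * 8)
  border <- which(!ef$myocardium, arr.ind = TRUE)
  expect_true(all(apply(border, 1, function(i) any(i %in% c(1, 10)))))
  tiny <- roi_set(matrix(c(TRUE, rep(FALSE, 24)), 5, 5),
                  matrix(FALSE, 5, 5), lv_center = c(3, 3))
  expect_error(erode_borders(tiny, 2), "emptied")
})

test_that("sector partition covers the myocardium once with correct stats", {
  ds <- noise_free_phantom()
  rois <- ds$rois
  vals <- matrix(1, nrow(rois$myocardium), ncol(rois$myocardium))
  m <- parametric_map(vals)
  sp12 <- sector_partition(rois, 12, map = m)
  # every myocardial voxel in exactly one sector, none outside
  expect_true(all(sp12$sector_map[rois$myocardium] %in% 1:12))
  expect_true(all(sp12$sector_map[!rois$myocardium] == 0L))
  expect_equal(sum(sp12$stats$n), sum(rois$myocardium))
  # uniform map: every sector mean equals the global mean
  expect_true(all(abs(sp12$stats$mean - 1) < 1e-12))
  # single sector reduces to the myocardial mean
  sp1 <- sector_partition(rois, 1, map = m)
  expect_equal(sp1$stats$n, sum(rois$myocardium))
  # a wedge lesion elevates only the covering sectors (30-90 deg -> 2, 3)
  vals2 <- vals; vals2[ds$truth$enhanced_mask] <- 10
  st <- sector_partition(rois, 12, map = parametric_map(vals2))$stats
  elevated <- which(st$mean > 1.5)
  expect_setequal(elevated, c(2, 3))
})
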