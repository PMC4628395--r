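#' Myocardial region-of-interest set
#'
#' Holds the reader- or phantom-supplied masks for one short-axis slice: the
#' myocardium, a non-enhanced remote reference ROI (a subset of the
#' myocardium), an optional blood-pool sample, the LV centre, and an integer
#' label map (0 background, 1 non-enhanced myocardium, 2 enhanced) filled by
#' the classification functions.
#'
#' @param myocardium Logical myocardial mask.
#' @param remote_roi Logical mask, subset of `myocardium`.
#' @param blood_roi Optional logical blood-pool mask.
#' @param lv_center LV centre `c(row, col)` in voxel units.
#' @param labels Optional integer label map; defaults to
#'   `myocardium * 1L` (all myocardium non-enhanced).
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(myocardium, remote_roi, blood_roi = NULL, lv_center,
                    labels = NULL) {
  if (!is.logical(myocardium) || !is.matrix(myocardium))
    stop("`myocardium` must be a logical matrix", call. = FALSE)
  if (!is.logical(remote_roi) || !identical(dim(remote_roi), dim(myocardium)))
    stop("`remote_roi` must be a logical matrix matching `myocardium`",
         call. = FALSE)
  if (any(remote_roi & !myocardium))
    stop("`remote_roi` must be a subset of `myocardium`", call. = FALSE)
  if (!is.null(blood_roi) &&
      (!is.logical(blood_roi) || !identical(dim(blood_roi), dim(myocardium))))
    stop("`blood_roi` must match the myocardial mask shape", call. = FALSE)
  if (length(lv_center) != 2L || !all(is.finite(lv_center)))
    stop("`lv_center` must be c(row, col)", call. = FALSE)
  if (is.null(labels)) {
    labels <- matrix(0L, nrow(myocardium), ncol(myocardium))
    labels[myocardium] <- 1L
  }
  if (!identical(dim(labels), dim(myocardium)) ||
      any(labels[!myocardium] != 0L) || !all(labels %in% 0:2))
    stop("`labels` must be 0/1/2 and zero outside the myocardium",
         call. = FALSE)
  structure(list(myocardium = myocardium, remote_roi = remote_roi,
                 blood_roi = blood_roi, lv_center = as.numeric(lv_center),
                 labels = labels, threshold = NULL),
            class = "roi_set")
}

#' Classification threshold with provenance
#'
#' @param value Threshold value (percent for delta-S/S0 maps, signal units
#'   for LGE images).
#' @param rule Descriptor of how the threshold was derived, e.g.
#'   `"mean+5SD remote"`, `"mean+3SD controls"`, `"fixed"`.
#' @param provenance List of the statistics that produced the value.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(value, rule = "fixed", provenance = list()) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("`value` must be a single finite number", call. = FALSE)
  structure(list(value = value, rule = rule, provenance = provenance),
            class = "threshold_spec")
}

#' Fixed clinical delta-S/S0 enhancement threshold
#'
#' The default enhancement cutoff applied to delta-S/S0 maps when no control
#' cohort or remote reference is supplied: 197 %, a healthy-control-derived
#' clinical value (control-cohort mean + 3 SD).
#'
#' @return A [threshold_spec()] with rule `"fixed"`.
#' @export
fixed_delta_s_threshold <- function() {
  threshold_spec(197, rule = "fixed",
                 provenance = list(note = "healthy-control cohort default"))
}

#' Control-cohort delta-S/S0 threshold (mean + 3 SD of subject means)
#'
#' Derives the enhancement threshold from per-subject mean delta-S/S0
#' values of a healthy control cohort as the across-subject mean plus three
#' sample standard deviations.
#'
#' @param control_subject_means Numeric vector (>= 2 subjects) of per-subject
#'   mean delta-S/S0 values in percent.
#' @return A [threshold_spec()] with rule `"mean+3SD controls"`.
#' @examples
#' derive_delta_s_threshold(c(100, 110, 120, 130, 140))  # 167.43 %
#' @export
derive_delta_s_threshold <- function(control_subject_means) {
  x <- control_subject_means
  if (!is.numeric(x) || length(x) < 2L || !all(is.finite(x)))
    stop("need >= 2 finite per-subject means", call. = FALSE)
  threshold_spec(mean(x) + 3 * stats::sd(x), rule = "mean+3SD controls",
                 provenance = list(n = length(x), mean = mean(x),
                                   sd = stats::sd(x), n_sd = 3))
}

#' ROI-referenced threshold: mean + n SD of a reference region
#'
#' Computes a threshold from the valid map voxels inside a reference ROI as
#' `mean + n_sd * SD` (sample SD). This is the LGE "5 SD" enhancement rule
#' when applied to an LGE image with `n_sd = 5`, and the remote-referenced
#' delta-S/S0 rule used by the phantom pipeline with `n_sd = 2`.
#'
#' @param map A [parametric_map()] (or numeric matrix).
#' @param roi Logical reference mask with at least 2 valid voxels.
#' @param n_sd Number of standard deviations above the ROI mean.
#' @param rule Rule label stored in the result.
#' @return A [threshold_spec()].
#' @export
derive_roi_threshold <- function(map, roi, n_sd,
                                 rule = sprintf("mean+%gSD remote", n_sd)) {
  m <- as_map_matrix(map, "map")
  if (!is.logical(roi) || !identical(dim(roi), dim(m$values)))
    stop("`roi` must be a logical mask matching the map", call. = FALSE)
  v <- m$values[roi & m$valid_mask]
  if (length(v) < 2L)
    stop("reference ROI must contain at least 2 valid voxels", call. = FALSE)
  threshold_spec(mean(v) + n_sd * stats::sd(v), rule = rule,
                 provenance = list(n = length(v), mean = mean(v),
                                   sd = stats::sd(v), n_sd = n_sd))
}

classify_above <- function(map, rois, threshold) {
  m <- as_map_matrix(map, "map")
  valid_myo <- rois$myocardium & m$valid_mask
  labels <- matrix(0L, nrow(m$values), ncol(m$values))
  labels[valid_myo] <- 1L
  labels[valid_myo & m$values > threshold$value] <- 2L
  out <- rois
  out$labels <- labels
  out$threshold <- threshold
  out
}

#' Classify enhanced myocardium on an LGE image (n SD rule)
#'
#' Myocardial voxels with signal intensity strictly greater than the remote
#' ROI mean plus `n_sd` (default 5) sample standard deviations are labelled
#' enhanced; remaining valid myocardial voxels are labelled non-enhanced.
#' The derived threshold is recorded on the returned ROI set.
#'
#' @param lge LGE image as a [parametric_map()] or numeric matrix.
#' @param rois A [roi_set()] whose `remote_roi` has >= 2 valid voxels.
#' @param n_sd Number of SDs above the remote mean (default 5).
#' @return The [roi_set()] with `labels` filled and `threshold` set.
#' @export
classify_lge <- function(lge, rois, n_sd = 5) {
  if (!inherits(rois, "roi_set")) stop("expected a `roi_set`", call. = FALSE)
  thr <- derive_roi_threshold(lge, rois$remote_roi, n_sd,
                              rule = sprintf("mean+%gSD remote", n_sd))
  classify_above(lge, rois, thr)
}

#' Classify enhanced myocardium on a delta-S/S0 map
#'
#' Valid myocardial voxels strictly above the threshold are labelled
#' enhanced (label 2); valid non-enhanced myocardium gets label 1; invalid
#' voxels keep label 0 and are excluded from both the numerator and the
#' denominator of downstream area statistics.
#'
#' @param dsmap Delta-S/S0 map in percent ([parametric_map()]).
#' @param rois A [roi_set()].
#' @param threshold A [threshold_spec()]; see [fixed_delta_s_threshold()],
#'   [derive_delta_s_threshold()], [derive_roi_threshold()].
#' @return The [roi_set()] with `labels` filled and `threshold` set.
#' @export
classify_delta_s <- function(dsmap, rois, threshold = fixed_delta_s_threshold()) {
  if (!inherits(rois, "roi_set")) stop("expected a `roi_set`", call. = FALSE)
  if (!inherits(threshold, "threshold_spec"))
    stop("expected a `threshold_spec`", call. = FALSE)
  m <- as_map_matrix(dsmap, "dsmap")
  if (!any(rois$myocardium & m$valid_mask))
    stop("no valid myocardial voxels in the map", call. = FALSE)
  classify_above(m, rois, threshold)
}

#' Erode the myocardial borders of an ROI set
#'
#' Morphologically erodes the myocardial mask by `n_voxels` (disc
#' structuring element of radius `n_voxels`), the border adjustment used to
#' exclude blood-pool and pleural-space partial-volume voxels at the
#' endocardial and epicardial edges. Labels and the remote ROI are
#' restricted to the eroded mask; `n_voxels = 0` is the identity.
#'
#' @param rois A [roi_set()].
#' @param n_voxels Non-negative erosion depth in voxels.
#' @return The eroded [roi_set()].
#' @export
erode_borders <- function(rois, n_voxels = 1) {
  if (!inherits(rois, "roi_set")) stop("expected a `roi_set`", call. = FALSE)
  if (n_voxels < 0) stop("`n_voxels` must be >= 0", call. = FALSE)
  if (n_voxels == 0) return(rois)
  brush <- EBImage::makeBrush(2 * n_voxels + 1, shape = "disc")
  # pad with background so voxels at the image edge erode too
  nr <- nrow(rois$myocardium); nc <- ncol(rois$myocardium)
  padded <- matrix(0, nr + 2 * n_voxels, nc + 2 * n_voxels)
  padded[n_voxels + seq_len(nr), n_voxels + seq_len(nc)] <-
    rois$myocardium * 1
  er_pad <- EBImage::erode(padded, brush) > 0.5
  eroded <- er_pad[n_voxels + seq_len(nr), n_voxels + seq_len(nc)]
  if (!any(eroded))
    stop("erosion emptied the myocardial mask", call. = FALSE)
  out <- rois
  out$myocardium <- eroded
  out$remote_roi <- rois$remote_roi & eroded
  out$labels[!eroded] <- 0L
  out
}

#' Circumferential sector partition and per-sector statistics
#'
#' Assigns every myocardial voxel to one of `n_sectors` equal
#' circumferential sectors by its angle about the LV centre (sector 1
#' starts at the image +x axis, counter-clockwise) and, when a map is
#' supplied, tabulates the per-sector mean and SD of its valid voxels.
#' Sectors containing no myocardial voxels are reported with `NA`
#' statistics rather than raised as errors.
#'
#' @param rois A [roi_set()] with a defined `lv_center`.
#' @param n_sectors Number of sectors (>= 1; clinical convention is 12).
#' @param map Optional [parametric_map()] to summarize per sector.
#' @return A list with `sector_map` (integer matrix, 0 outside the
#'   myocardium) and, when `map` is given, `stats` (data.frame with
#'   `sector`, `n`, `mean`, `sd`).
#' @export
sector_partition <- function(rois, n_sectors = 12, map = NULL) {
  if (!inherits(rois, "roi_set")) stop("expected a `roi_set`", call. = FALSE)
  n_sectors <- as.integer(n_sectors)
  if (n_sectors < 1L) stop("`n_sectors` must be >= 1", call. = FALSE)
  pol <- voxel_polar(nrow(rois$myocardium), ncol(rois$myocardium),
                     rois$lv_center)
  width <- 360 / n_sectors
  sector_map <- matrix(0L, nrow(rois$myocardium), ncol(rois$myocardium))
  sector_map[rois$myocardium] <-
    pmin(floor(pol$theta[rois$myocardium] / width), n_sectors - 1L) + 1L
  out <- list(sector_map = sector_map)
  if (!is.null(map)) {
    m <- as_map_matrix(map, "map")
    if (!identical(dim(m$values), dim(sector_map)))
      stop("`map` must match the mask shape", call. = FALSE)
    out$stats <- do.call(rbind, lapply(seq_len(n_sectors), function(s) {
      v <- m$values[sector_map == s & m$valid_mask]
      data.frame(sector = s, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_)
    }))
  }
  out
}
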