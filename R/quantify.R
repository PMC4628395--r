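#' Enhanced-area report from a classified ROI set
#'
#' The enhanced area is the percentage of all (valid, labelled) myocardial
#' voxels classified as enhanced: `100 * n_enhanced / n_myocardium`, where
#' the denominator counts voxels with label 1 or 2 (invalid voxels carry
#' label 0 and are excluded from numerator and denominator alike).
#'
#' @param rois A classified [roi_set()] (labels filled).
#' @param method Label source recorded in the report, `"deltaS"` or `"LGE"`.
#' @return A list of class `lesion_report`: `enhanced_area_pct`,
#'   `n_enhanced`, `n_myocardium`, `method`.
#' @export
enhanced_area <- function(rois, method = c("deltaS", "LGE")) {
  if (!inherits(rois, "roi_set")) stop("expected a `roi_set`", call. = FALSE)
  method <- match.arg(method)
  n_myo <- sum(rois$labels >= 1L)
  if (n_myo == 0L)
    stop("no labelled myocardial voxels", call. = FALSE)
  n_enh <- sum(rois$labels == 2L)
  structure(list(enhanced_area_pct = 100 * n_enh / n_myo,
                 n_enhanced = n_enh, n_myocardium = n_myo,
                 method = method),
            class = "lesion_report")
}

#' @export
print.lesion_report <- function(x, ...) {
  cat(sprintf("<lesion_report> %s: %.2f%% enhanced (%d / %d voxels)\n",
              x$method, x$enhanced_area_pct, x$n_enhanced, x$n_myocardium))
  invisible(x)
}

#' Transmurality of enhancement along the central radial direction
#'
#' Transmurality is the percentage of the wall thickness occupied by
#' enhancement along the radial direction at the centre of the enhanced
#' area. The centre angle is the circular mean of the enhanced voxels'
#' angles about the LV centre (robust to wrap-around); a ray cast from the
#' LV centre at that angle is sampled every `step` voxels with
#' nearest-voxel label lookup, and the result is
#' `100 * (enhanced samples) / (myocardial samples)` along the ray.
#'
#' With no enhanced voxel the quantity is undefined (distinct from 0 %) and
#' an error of class `bssfp2pt_no_enhancement` is signalled.
#'
#' @param rois A classified [roi_set()].
#' @param step Ray sampling step in voxels (default 0.25).
#' @return Transmurality in percent, with the centre angle attached as
#'   attribute `"center_angle_deg"`.
#' @export
transmurality <- function(rois, step = 0.25) {
  if (!inherits(rois, "roi_set")) stop("expected a `roi_set`", call. = FALSE)
  enh <- which(rois$labels == 2L, arr.ind = TRUE)
  if (nrow(enh) == 0L)
    stop(structure(class = c("bssfp2pt_no_enhancement", "error", "condition"),
                   list(message = paste("transmurality is undefined without",
                                        "enhanced voxels"),
                        call = sys.call())))
  cy <- rois$lv_center[1]; cx <- rois$lv_center[2]
  theta <- (atan2(cy - enh[, 1], enh[, 2] - cx) * 180 / pi) %% 360
  ang <- circular_mean_deg(theta)
  rad <- ang * pi / 180
  rmax <- sqrt(nrow(rois$labels)^2 + ncol(rois$labels)^2)
  r <- seq(0, rmax, by = step)
  rows <- round(cy - r * sin(rad))
  cols <- round(cx + r * cos(rad))
  inside <- rows >= 1 & rows <= nrow(rois$labels) &
    cols >= 1 & cols <= ncol(rois$labels)
  lab <- rois$labels[cbind(rows[inside], cols[inside])]
  n_myo <- sum(lab >= 1L)
  if (n_myo == 0L)
    stop("central ray does not traverse the myocardium", call. = FALSE)
  out <- 100 * sum(lab == 2L) / n_myo
  attr(out, "center_angle_deg") <- ang
  out
}

# Scalar gadolinium partition coefficient from four T1 values (ms).
gpc_scalar <- function(t1_pre, t1_post, blood_t1_pre, blood_t1_post) {
  (1 / t1_post - 1 / t1_pre) / (1 / blood_t1_post - 1 / blood_t1_pre)
}

#' Median blood T1 values from a blood-pool ROI
#'
#' @param t1_pre_map,t1_post_map Pre/post-contrast T1 maps
#'   ([parametric_map()], ms).
#' @param blood_roi Logical blood-pool mask.
#' @return Named numeric vector `c(pre = ..., post = ...)` of ROI medians.
#' @export
blood_t1_scalars <- function(t1_pre_map, t1_post_map, blood_roi) {
  pre <- as_map_matrix(t1_pre_map, "t1_pre_map")
  post <- as_map_matrix(t1_post_map, "t1_post_map")
  sel_pre <- blood_roi & pre$valid_mask
  sel_post <- blood_roi & post$valid_mask
  if (!any(sel_pre) || !any(sel_post))
    stop("blood ROI contains no valid T1 voxels", call. = FALSE)
  c(pre = stats::median(pre$values[sel_pre]),
    post = stats::median(post$values[sel_post]))
}

#' Gadolinium partition coefficient map
#'
#' Computes the per-voxel gadolinium partition coefficient
#' \deqn{GPC = \Delta R_{1,myocardium} / \Delta R_{1,blood}} with
#' \eqn{R_1 = 1/T_1}, from pre/post-contrast myocardial T1 maps and scalar
#' blood T1 values (typically blood-ROI medians, see [blood_t1_scalars()]).
#' The quantity is invariant under a common rescaling of all four T1 inputs
#' (ms vs s). Myocardial voxels with non-positive delta-R1 are marked
#' invalid.
#'
#' @param t1_pre_map,t1_post_map Myocardial T1 maps ([parametric_map()] or
#'   matrices, ms).
#' @param blood_t1_pre,blood_t1_post Scalar blood T1 values (ms); the
#'   post-contrast value must be smaller (blood delta-R1 > 0).
#' @param myocardium Logical myocardial mask.
#' @return A dimensionless [parametric_map()] valid on the myocardium.
#' @examples
#' # worked scalar example: myocardium 1000 -> 500 ms, blood 1600 -> 400 ms
#' m <- matrix(1000, 1, 1); p <- matrix(500, 1, 1)
#' gpc_map(m, p, 1600, 400, matrix(TRUE, 1, 1))$values  # 0.5333
#' @export
gpc_map <- function(t1_pre_map, t1_post_map, blood_t1_pre, blood_t1_post,
                    myocardium) {
  pre <- as_map_matrix(t1_pre_map, "t1_pre_map")
  post <- as_map_matrix(t1_post_map, "t1_post_map")
  if (!identical(dim(pre$values), dim(post$values)) ||
      !identical(dim(pre$values), dim(myocardium)))
    stop("T1 maps and myocardial mask must share one shape", call. = FALSE)
  dr1_blood <- 1 / blood_t1_post - 1 / blood_t1_pre
  if (!is.finite(dr1_blood) || dr1_blood <= 0)
    stop("blood delta-R1 must be positive (post-contrast T1 < pre-contrast)",
         call. = FALSE)
  ok <- myocardium & pre$valid_mask & post$valid_mask &
    pre$values > 0 & post$values > 0
  vals <- matrix(NA_real_, nrow(pre$values), ncol(pre$values))
  vals[ok] <- (1 / post$values[ok] - 1 / pre$values[ok]) / dr1_blood
  valid <- ok & is.finite(vals) & !is.na(vals) & (vals > 0)
  vals[!valid] <- NA_real_
  parametric_map(vals, valid, units = "")
}

#' DICE similarity coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Two empty masks are defined as
#' perfectly agreeing (coefficient 1, flagged with attribute
#' `"both_empty"`).
#'
#' @param a,b Logical matrices of one shape.
#' @return Coefficient in `[0, 1]`.
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' dice_coefficient(a, a)  # 1
#' @export
dice_coefficient <- function(a, b) {
  if (!is.logical(a) || !is.logical(b) || !identical(dim(a), dim(b)))
    stop("`a` and `b` must be logical masks of one shape", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) {
    out <- 1
    attr(out, "both_empty") <- TRUE
    return(out)
  }
  2 * sum(a & b) / (na + nb)
}
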