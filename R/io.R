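#' Read an image volume from NIfTI
#'
#' Reads a NIfTI file and returns the voxel data with whatever geometry
#' metadata the header carries. Metadata missing from the header is
#' returned as `NULL`, never silently defaulted.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return List with `data` (numeric array), `pixdim` (voxel spacing or
#'   `NULL`) and `metadata` (flip angle / TR if a JSON sidecar records
#'   them, else `NULL`s).
#' @export
read_image_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("unreadable NIfTI '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  hdr <- RNifti::niftiHeader(img)
  side <- sidecar_path(path)
  meta <- list(flip_angle = NULL, tr = NULL, units = NULL)
  if (file.exists(side)) {
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (k in names(meta)) if (!is.null(sc[[k]])) meta[[k]] <- sc[[k]]
  }
  list(data = array(as.numeric(img), dim = dim(img)),
       pixdim = hdr$pixdim[2:(1 + length(dim(img)))],
       metadata = meta)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write an image volume (matrix, array or parametric map) as NIfTI
#'
#' Parametric maps are written with invalid voxels as `NaN` and a JSON
#' sidecar recording units and any processing history attached to the map.
#'
#' @param x Numeric matrix/array or [parametric_map()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @param sidecar Optional named list merged into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_image_volume <- function(x, path, sidecar = NULL) {
  if (inherits(x, "parametric_map")) {
    vals <- x$values
    vals[!x$valid_mask] <- NaN
    sidecar <- c(list(units = x$units), sidecar)
    RNifti::writeNifti(vals, path)
  } else {
    RNifti::writeNifti(x, path)
  }
  if (!is.null(sidecar))
    jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a phantom dataset to a directory
#'
#' Cine phase stacks are written as 3-D NIfTI volumes (`cine_low.nii`,
#' `cine_high.nii`), maps as 2-D volumes, masks as an integer label volume
#' (1 myocardium, 2 remote ROI, 3 blood ROI bits are separate files), and
#' the ground-truth record as JSON.
#'
#' @param dataset A [generate_phantom()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "phantom_dataset"))
    stop("expected a `phantom_dataset`", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stack <- function(phases) {
    arr <- array(0, c(dim(phases[[1]]), length(phases)))
    for (i in seq_along(phases)) arr[, , i] <- phases[[i]]
    arr
  }
  cp <- dataset$cine_pair
  write_image_volume(stack(cp$low_phases), file.path(dir, "cine_low.nii"),
                     sidecar = list(flip_angle = cp$low_angle,
                                    tr = dataset$spec$acq_low$tr))
  write_image_volume(stack(cp$high_phases), file.path(dir, "cine_high.nii"),
                     sidecar = list(flip_angle = cp$high_angle,
                                    tr = dataset$spec$acq_high$tr))
  write_image_volume(dataset$lge_image, file.path(dir, "lge.nii"))
  write_image_volume(dataset$t1_pre, file.path(dir, "t1_pre.nii"))
  write_image_volume(dataset$t1_post, file.path(dir, "t1_post.nii"))
  r <- dataset$rois
  write_image_volume(r$myocardium * 1L, file.path(dir, "mask_myocardium.nii"))
  write_image_volume(r$remote_roi * 1L, file.path(dir, "mask_remote.nii"))
  if (!is.null(r$blood_roi))
    write_image_volume(r$blood_roi * 1L, file.path(dir, "mask_blood.nii"))
  truth <- dataset$truth
  truth$enhanced_mask <- NULL  # stored as its own volume
  write_image_volume(dataset$truth$enhanced_mask * 1L,
                     file.path(dir, "mask_truth_enhanced.nii"))
  jsonlite::write_json(c(truth, list(lv_center = r$lv_center)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Pipeline configuration
#'
#' Collects every tunable of the analysis pipeline in one serializable
#' object; `load_config(save_config(c))` round-trips.
#'
#' @param threshold_rule Delta-S/S0 threshold rule: `"fixed"` (use
#'   `threshold_value`), `"remote_nsd"` (remote-ROI mean + `delta_s_n_sd`
#'   SD on the processed map) or `"controls"` (requires `control_means`).
#' @param threshold_value Fixed threshold in percent (rule `"fixed"`).
#' @param control_means Per-subject control means (rule `"controls"`).
#' @param delta_s_n_sd SDs above the remote mean for rule `"remote_nsd"`.
#' @param lge_n_sd SDs above the remote mean for LGE classification.
#' @param s5_floor Reference-signal validity floor (see [delta_s_map()]).
#' @param median_filter Apply the 3x2 median filter before classification.
#' @param kernel_rows,kernel_cols Median-filter kernel.
#' @param erode_voxels Myocardial border erosion depth.
#' @param n_sectors Circumferential sector count.
#' @param seed Seed recorded for provenance.
#' @param verbose Log one structured line per stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_rule = c("remote_nsd", "fixed",
                                               "controls"),
                            threshold_value = 197,
                            control_means = NULL,
                            delta_s_n_sd = 2, lge_n_sd = 5,
                            s5_floor = 1e-4,
                            median_filter = TRUE,
                            kernel_rows = 3, kernel_cols = 2,
                            erode_voxels = 1, n_sectors = 12,
                            seed = 1, verbose = FALSE) {
  threshold_rule <- match.arg(threshold_rule)
  if (threshold_rule == "controls" &&
      (is.null(control_means) || length(control_means) < 2))
    stop("rule 'controls' needs >= 2 control subject means", call. = FALSE)
  structure(list(threshold_rule = threshold_rule,
                 threshold_value = threshold_value,
                 control_means = control_means,
                 delta_s_n_sd = delta_s_n_sd, lge_n_sd = lge_n_sd,
                 s5_floor = s5_floor, median_filter = median_filter,
                 kernel_rows = kernel_rows, kernel_cols = kernel_cols,
                 erode_voxels = erode_voxels, n_sectors = n_sectors,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path Output path; `.yaml`/`.yml` writes YAML, anything else JSON.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  x <- x[!vapply(x, is.null, logical(1))]
  do.call(pipeline_config, x)
}

log_stage <- function(verbose, stage, ...) {
  if (verbose)
    message(sprintf("[%s] %s", stage,
                    paste(sprintf("%s=%s", names(list(...)),
                                  unlist(list(...))), collapse = " ")))
}

#' Run the full two-point bSSFP analysis on one slice
#'
#' Sequences the method end to end: per-phase delta-S/S0 maps from the cine
#' pair, averaging over phases, optional 3x2 median filtering, myocardial
#' border erosion, threshold derivation, enhancement classification, and
#' quantification (enhanced area, transmurality, sector statistics). When
#' an LGE image is supplied the 5 SD LGE classification, its
#' quantification, and the DICE overlap between the two enhanced masks are
#' added; when T1 maps and a blood ROI are supplied, a GPC map and its
#' tissue medians are added. Deterministic given its inputs.
#'
#' @param cine_pair A [cine_slice_pair()].
#' @param rois A [roi_set()].
#' @param config A [pipeline_config()].
#' @param lge Optional LGE [parametric_map()].
#' @param t1_pre,t1_post Optional pre/post-contrast T1 maps.
#' @return A list of class `slice_report` with the processed map, label
#'   maps, thresholds, lesion reports and summary scalars.
#' @export
analyze_slice <- function(cine_pair, rois, config = pipeline_config(),
                          lge = NULL, t1_pre = NULL, t1_post = NULL) {
  if (!inherits(cine_pair, "cine_slice_pair"))
    stop("expected a `cine_slice_pair`", call. = FALSE)
  if (!inherits(rois, "roi_set")) stop("expected a `roi_set`", call. = FALSE)
  if (!inherits(config, "pipeline_config"))
    stop("expected a `pipeline_config`", call. = FALSE)
  v <- config$verbose

  phase_maps <- Map(function(hi, lo)
    delta_s_map(hi, lo, s5_floor = config$s5_floor),
    cine_pair$high_phases, cine_pair$low_phases)
  dsmap <- average_phase_maps(phase_maps)
  log_stage(v, "map", phases = length(phase_maps),
            valid = sum(dsmap$valid_mask))
  if (config$median_filter)
    dsmap <- median_filter_map(dsmap, config$kernel_rows, config$kernel_cols)

  work_rois <- erode_borders(rois, config$erode_voxels)
  thr <- switch(config$threshold_rule,
    fixed = threshold_spec(config$threshold_value, rule = "fixed"),
    controls = derive_delta_s_threshold(config$control_means),
    remote_nsd = derive_roi_threshold(dsmap, work_rois$remote_roi,
                                      config$delta_s_n_sd))
  ds_rois <- classify_delta_s(dsmap, work_rois, thr)
  ds_report <- enhanced_area(ds_rois, method = "deltaS")
  ds_trans <- tryCatch(as.numeric(transmurality(ds_rois)),
                       error = function(e) NA_real_)
  log_stage(v, "classify_deltaS", rule = thr$rule,
            threshold = signif(thr$value, 6),
            enhanced = ds_report$n_enhanced)
  sectors <- sector_partition(ds_rois, config$n_sectors, map = dsmap)

  report <- list(
    dsmap = dsmap,
    ds_labels = ds_rois$labels,
    ds_threshold = thr,
    ds_report = ds_report,
    ds_transmurality_pct = ds_trans,
    sector_stats = sectors$stats,
    config = config)

  if (!is.null(lge)) {
    lge_rois <- classify_lge(lge, work_rois, n_sd = config$lge_n_sd)
    report$lge_labels <- lge_rois$labels
    report$lge_threshold <- lge_rois$threshold
    report$lge_report <- enhanced_area(lge_rois, method = "LGE")
    report$lge_transmurality_pct <-
      tryCatch(as.numeric(transmurality(lge_rois)),
               error = function(e) NA_real_)
    report$dice_enhanced <- dice_coefficient(ds_rois$labels == 2L,
                                             lge_rois$labels == 2L)
    log_stage(v, "classify_LGE",
              threshold = signif(lge_rois$threshold$value, 6),
              enhanced = report$lge_report$n_enhanced,
              dice = signif(report$dice_enhanced, 4))
  } else {
    log_stage(v, "classify_LGE", skipped = TRUE)
  }

  if (!is.null(t1_pre) && !is.null(t1_post) && !is.null(rois$blood_roi)) {
    bt1 <- blood_t1_scalars(t1_pre, t1_post, rois$blood_roi)
    gmap <- gpc_map(t1_pre, t1_post, bt1[["pre"]], bt1[["post"]],
                    work_rois$myocardium)
    report$gpc_map <- gmap
    report$blood_t1 <- bt1
    sel_enh <- report$gpc_map$valid_mask & ds_rois$labels == 2L
    sel_rem <- report$gpc_map$valid_mask & ds_rois$labels == 1L
    report$gpc_median <- c(
      enhanced = if (any(sel_enh)) stats::median(gmap$values[sel_enh])
                 else NA_real_,
      non_enhanced = if (any(sel_rem)) stats::median(gmap$values[sel_rem])
                     else NA_real_)
    log_stage(v, "gpc", blood_pre = bt1[["pre"]], blood_post = bt1[["post"]])
  }
  class(report) <- "slice_report"
  report
}

#' @export
print.slice_report <- function(x, ...) {
  cat(sprintf("<slice_report> deltaS/S0: %.2f%% enhanced (thr %.4g%% [%s])\n",
              x$ds_report$enhanced_area_pct, x$ds_threshold$value,
              x$ds_threshold$rule))
  if (!is.null(x$lge_report))
    cat(sprintf("  LGE: %.2f%% enhanced; DICE(enhanced) %.3f\n",
                x$lge_report$enhanced_area_pct, x$dice_enhanced))
  invisible(x)
}

#' Run the pipeline on a phantom dataset and write a report bundle
#'
#' Convenience wrapper: analyzes a [generate_phantom()] dataset with
#' [analyze_slice()] and, when `out_dir` is given, writes the processed
#' delta-S/S0 map, label maps and a JSON report with full provenance
#' (thresholds, counts, config, seed). Byte-identical outputs for identical
#' config and seed.
#'
#' @param dataset A `phantom_dataset`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return The `slice_report`, invisibly when writing.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         out_dir = NULL) {
  if (!inherits(dataset, "phantom_dataset"))
    stop("expected a `phantom_dataset`", call. = FALSE)
  rep <- analyze_slice(dataset$cine_pair, dataset$rois, config,
                       lge = dataset$lge_image,
                       t1_pre = dataset$t1_pre, t1_post = dataset$t1_post)
  if (is.null(out_dir)) return(rep)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_image_volume(rep$dsmap, file.path(out_dir, "delta_s_map.nii"),
                     sidecar = list(
                       phases_averaged = dataset$spec$n_phases,
                       median_filter = config$median_filter,
                       threshold = rep$ds_threshold$value,
                       threshold_rule = rep$ds_threshold$rule))
  write_image_volume(rep$ds_labels, file.path(out_dir, "labels_deltaS.nii"))
  if (!is.null(rep$lge_labels))
    write_image_volume(rep$lge_labels, file.path(out_dir, "labels_lge.nii"))
  json_report <- list(
    seed = config$seed,
    config = unclass(config),
    ds_threshold = unclass(rep$ds_threshold),
    ds = unclass(rep$ds_report),
    ds_transmurality_pct = rep$ds_transmurality_pct,
    lge_threshold = if (!is.null(rep$lge_threshold))
      unclass(rep$lge_threshold),
    lge = if (!is.null(rep$lge_report)) unclass(rep$lge_report),
    lge_transmurality_pct = rep$lge_transmurality_pct,
    dice_enhanced = rep$dice_enhanced,
    gpc_median = as.list(rep$gpc_median),
    truth = list(enhanced_area_pct = dataset$truth$enhanced_area_pct,
                 transmurality_pct = dataset$truth$transmurality_pct))
  jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(rep)
}
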