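# Shared fixtures: built in code at test time.

default_acq5 <- function() acq_params(flip_angle = 5)
default_acq45 <- function() acq_params(flip_angle = 45)

remote_tissue <- function() phantom_tissues()$remote
lesion_tissue <- function() phantom_tissues()$lesion

# Noise-free default-geometry phantom, memoised per transmurality so several
# test files can reuse it without regenerating.
.phantom_cache <- new.env(parent = emptyenv())
noise_free_phantom <- function(transmurality = 1, lesion_theta = c(30, 90)) {
  key <- paste0("t", transmurality, "_", paste(lesion_theta, collapse = "_"))
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(phantom_spec(
      noise_sigma = 0, lesion_theta = lesion_theta,
      lesion_transmurality = transmurality, seed = 42))
  .phantom_cache[[key]]
}

# Pipeline settings for noise-free inputs: no smoothing, no border erosion
# (both exist to combat noise and partial volume, which a noise-free
# phantom does not have).
noise_free_config <- function(...) {
  pipeline_config(median_filter = FALSE, erode_voxels = 0, ...)
}

make_rois <- function(n = 8) {
  myo <- matrix(TRUE, n, n)
  remote <- matrix(FALSE, n, n); remote[1:2, ] <- TRUE
  roi_set(myocardium = myo, remote_roi = remote,
          lv_center = c((n + 1) / 2, (n + 1) / 2))
}

# Brute-force count of annular-wedge voxels: the geometric oracle for the
# phantom's enhanced-area truth, computed by direct looping independent of
# the phantom's vectorized masks.
brute_force_wedge_pct <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  cy <- spec$center[1]; cx <- spec$center[2]
  outer_r <- spec$endo_radius +
    spec$lesion_transmurality * (spec$epi_radius - spec$endo_radius)
  n_myo <- 0L; n_wedge <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    dx <- c - cx; dy <- cy - r
    rad <- sqrt(dx^2 + dy^2)
    if (rad >= spec$endo_radius && rad < spec$epi_radius) {
      n_myo <- n_myo + 1L
      th <- (atan2(dy, dx) * 180 / pi) %% 360
      if (th >= spec$lesion_theta[1] && th < spec$lesion_theta[2] &&
          rad < outer_r)
        n_wedge <- n_wedge + 1L
    }
  }
  100 * n_wedge / n_myo
}
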