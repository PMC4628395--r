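#' Normalized signal-change map from one image pair
#'
#' Computes the voxel-wise normalized change in signal between a
#' high-flip-angle (MT/T1/T2-weighted) and a low-flip-angle (proton-density
#' reference) magnitude image,
#' \deqn{(\Delta S/S_0)_i = (S_{high} - S_{low}) / S_{low} \times 100 \ (\%)}
#' Voxels whose reference signal falls below `s5_floor` are marked invalid
#' rather than computed, preventing division blow-ups in the low-SNR
#' reference image; they stay excluded from all downstream statistics.
#' Negative values are retained - they simply fall below any enhancement
#' threshold.
#'
#' @param high_phase,low_phase Magnitude images (numeric matrices or
#'   [parametric_map()]s) of one cardiac phase at the high and low flip
#'   angle.
#' @param s5_floor Positive reference-signal validity floor, in the signal
#'   units of the images (a practical choice is about twice the noise
#'   standard deviation).
#' @return A [parametric_map()] in percent.
#' @examples
#' hi <- matrix(60, 2, 2); lo <- matrix(20, 2, 2)
#' delta_s_map(hi, lo, s5_floor = 1)$values[1, 1]  # 200
#' @export
delta_s_map <- function(high_phase, low_phase, s5_floor = 1e-6) {
  hi <- as_map_matrix(high_phase, "high_phase")
  lo <- as_map_matrix(low_phase, "low_phase")
  if (!identical(dim(hi$values), dim(lo$values)))
    stop("high/low images must share one shape", call. = FALSE)
  if (!is.numeric(s5_floor) || length(s5_floor) != 1L || s5_floor <= 0)
    stop("`s5_floor` must be a single positive number", call. = FALSE)
  valid <- hi$valid_mask & lo$valid_mask & (lo$values >= s5_floor)
  vals <- matrix(NA_real_, nrow(hi$values), ncol(hi$values))
  vals[valid] <- (hi$values[valid] - lo$values[valid]) / lo$values[valid] * 100
  parametric_map(vals, valid, units = "%")
}

#' Average parametric maps across cardiac phases
#'
#' Voxel-wise arithmetic mean over a list of maps (typically delta-S/S0 maps
#' from three motion-free diastolic phases, averaged to reduce random
#' noise). A voxel is valid in the output only where it is valid in every
#' input (mask intersection).
#'
#' @param maps Non-empty list of [parametric_map()]s sharing one shape.
#' @return A [parametric_map()] with the units of the first input.
#' @export
average_phase_maps <- function(maps) {
  if (!is.list(maps) || length(maps) == 0L)
    stop("`maps` must be a non-empty list of parametric maps", call. = FALSE)
  maps <- lapply(maps, as_map_matrix, what = "maps[[i]]")
  dims <- lapply(maps, function(m) dim(m$values))
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop("all maps must share one shape", call. = FALSE)
  valid <- Reduce(`&`, lapply(maps, `[[`, "valid_mask"))
  acc <- Reduce(`+`, lapply(maps, function(m) {
    v <- m$values; v[!is.finite(v)] <- 0; v
  }))
  vals <- acc / length(maps)
  vals[!valid] <- NA_real_
  parametric_map(vals, valid, units = maps[[1]]$units)
}

#' Sliding-window median filter with validity-mask support
#'
#' Median filters a parametric map with a rectangular kernel (default 3 rows
#' by 2 columns). Edges are handled by reflection. Invalid voxels are
#' excluded from every window, so the output at a voxel is the median of the
#' valid window members only; windows with no valid member produce an
#' invalid voxel. Even-count windows use the mean of the two middle order
#' statistics (the usual sample median).
#'
#' @param map A [parametric_map()] (or numeric matrix).
#' @param kernel_rows,kernel_cols Kernel dimensions (>= 1 and no larger than
#'   the image).
#' @return A filtered [parametric_map()].
#' @export
median_filter_map <- function(map, kernel_rows = 3, kernel_cols = 2) {
  m <- as_map_matrix(map, "map")
  nr <- nrow(m$values); nc <- ncol(m$values)
  kr <- as.integer(kernel_rows); kc <- as.integer(kernel_cols)
  if (kr < 1L || kc < 1L) stop("kernel dims must be >= 1", call. = FALSE)
  if (kr > nr || kc > nc)
    stop("kernel larger than image", call. = FALSE)

  # window offsets about the (upper-left-of-centre for even sizes) anchor
  ro <- seq.int(-((kr - 1L) %/% 2L), (kr - 1L) - (kr - 1L) %/% 2L)
  co <- seq.int(-((kc - 1L) %/% 2L), (kc - 1L) - (kc - 1L) %/% 2L)

  reflect_idx <- function(i, n) {
    # reflect without repeating the edge sample (n>1), e.g. 0 -> 2, n+1 -> n-1
    if (n == 1L) return(rep(1L, length(i)))
    j <- (i - 1L) %% (2L * (n - 1L))
    ifelse(j >= n, 2L * (n - 1L) - j, j) + 1L
  }

  vals <- m$values
  vals[!m$valid_mask] <- NA_real_
  stack <- matrix(NA_real_, nr * nc, length(ro) * length(co))
  k <- 0L
  for (dc in co) for (dr in ro) {
    k <- k + 1L
    rows <- reflect_idx(seq_len(nr) + dr, nr)
    cols <- reflect_idx(seq_len(nc) + dc, nc)
    stack[, k] <- vals[rows, cols]
  }
  med <- apply(stack, 1L, stats::median, na.rm = TRUE)
  out <- matrix(med, nr, nc)
  parametric_map(out, is.finite(out), units = m$units)
}
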