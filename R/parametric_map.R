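#' Per-voxel scalar field with a validity mask
#'
#' Container for 2-D parametric maps (delta-S/S0 in %, T1 in ms, GPC, LGE
#' signal): a numeric matrix plus a logical mask marking the voxels whose
#' values are defined. Invalid voxels are excluded from every downstream
#' statistic (classification numerators and denominators, sector means,
#' filter windows).
#'
#' @param values Numeric matrix of voxel values.
#' @param valid_mask Logical matrix of the same shape; defaults to
#'   `is.finite(values)`.
#' @param units Unit label, e.g. `"%"`, `"ms"`, `""` (dimensionless).
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(values, valid_mask = NULL, units = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  if (!is.logical(valid_mask) || !identical(dim(valid_mask), dim(values)))
    stop("`valid_mask` must be a logical matrix matching `values`",
         call. = FALSE)
  valid_mask <- valid_mask & is.finite(values)
  structure(list(values = values, valid_mask = valid_mask,
                 units = as.character(units)),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("<parametric_map> %d x %d voxels, units '%s'\n",
              nrow(x$values), ncol(x$values), x$units))
  cat(sprintf("  valid: %d/%d; range %.4g .. %.4g\n",
              sum(x$valid_mask), length(x$valid_mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

as_map_matrix <- function(x, what = "image") {
  if (inherits(x, "parametric_map")) return(x)
  if (is.matrix(x) && is.numeric(x)) return(parametric_map(x))
  stop(sprintf("`%s` must be a numeric matrix or parametric_map", what),
       call. = FALSE)
}

#' Matched low/high flip-angle cine phase stacks for one slice
#'
#' @param low_phases,high_phases Lists of magnitude images (numeric
#'   matrices), one per cardiac phase, at the low and high flip angle. All
#'   images must share one shape and the two lists one length.
#' @param low_angle,high_angle Excitation flip angles in degrees;
#'   `low_angle < high_angle`.
#' @param phase_indices Optional phase labels (defaults to `1:n`).
#' @return An object of class `cine_slice_pair`.
#' @export
cine_slice_pair <- function(low_phases, high_phases,
                            low_angle = 5, high_angle = 45,
                            phase_indices = NULL) {
  if (!is.list(low_phases) || !is.list(high_phases) ||
      length(low_phases) == 0L ||
      length(low_phases) != length(high_phases))
    stop("phase lists must be non-empty and of equal length", call. = FALSE)
  dims <- lapply(c(low_phases, high_phases), dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop("all phase images must share one shape", call. = FALSE)
  if (low_angle >= high_angle)
    stop("`low_angle` must be smaller than `high_angle`", call. = FALSE)
  if (is.null(phase_indices)) phase_indices <- seq_along(low_phases)
  structure(list(low_phases = low_phases, high_phases = high_phases,
                 low_angle = low_angle, high_angle = high_angle,
                 phase_indices = phase_indices),
            class = "cine_slice_pair")
}
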