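# Shared voxel geometry: one angle/radius convention for phantom,
# sector partition and transmurality.
#
# Rows index the image top-down, columns left-right (1-based). Angles are
# measured counter-clockwise from the image +x axis (increasing column),
# i.e. theta = atan2(center_row - row, col - center_col), reported in
# [0, 360) degrees.

voxel_polar <- function(nrow_img, ncol_img, center) {
  rows <- matrix(seq_len(nrow_img), nrow_img, ncol_img)
  cols <- matrix(seq_len(ncol_img), nrow_img, ncol_img, byrow = TRUE)
  x <- cols - center[2]
  y <- center[1] - rows
  list(radius = sqrt(x^2 + y^2),
       theta = (atan2(y, x) * 180 / pi) %% 360)
}

in_angular_interval <- function(theta, interval) {
  lo <- interval[1] %% 360
  hi <- interval[2] %% 360
  if (interval[2] - interval[1] >= 360) return(rep(TRUE, length(theta)) |
                                                 array(TRUE, dim = dim(theta)))
  if (lo <= hi) theta >= lo & theta < hi else theta >= lo | theta < hi
}

circular_mean_deg <- function(theta_deg) {
  th <- theta_deg * pi / 180
  (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi) %% 360
}
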