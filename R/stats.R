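#' Bland-Altman agreement analysis of paired measurements
#'
#' For per-subject pairs (a, b) computes differences `d = a - b`, the bias
#' (mean difference), 95 % limits of agreement `bias +/- 1.96 * SD(d)`
#' (sample SD), and the coefficient of variation, defined here as
#' `SD(d)` divided by the grand mean of the per-pair means. The per-pair
#' (mean, difference) table is returned for plotting.
#'
#' @param method_a,method_b Equal-length numeric vectors (n >= 2) of
#'   per-subject measurements (e.g. enhanced area % by delta-S/S0 and LGE).
#' @param subject_ids Optional subject labels.
#' @return An object of class `agreement_result`: `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `cov`, `n`, `table`.
#' @examples
#' bland_altman(c(10, 20, 30), c(12, 18, 33))
#' @export
bland_altman <- function(method_a, method_b, subject_ids = NULL) {
  a <- as.numeric(method_a); b <- as.numeric(method_b)
  if (length(a) != length(b) || length(a) < 2L)
    stop("need equal-length vectors with n >= 2", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("measurements must be finite", call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- seq_along(a)
  d <- a - b
  m <- (a + b) / 2
  bias <- mean(d)
  sd_d <- stats::sd(d)
  grand <- mean(m)
  cov <- if (grand == 0) {
    warning("grand mean is zero; coefficient of variation undefined",
            call. = FALSE)
    NA_real_
  } else sd_d / grand
  structure(list(bias = bias,
                 loa_low = bias - 1.96 * sd_d,
                 loa_high = bias + 1.96 * sd_d,
                 sd_diff = sd_d, cov = cov, n = length(a),
                 table = data.frame(subject = subject_ids, mean = m,
                                    difference = d)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> n=%d bias=%.4g LoA [%.4g, %.4g] CoV=%.4g\n",
    x$n, x$bias, x$loa_low, x$loa_high, x$cov))
  invisible(x)
}

#' Association between two paired measurement methods
#'
#' Pearson correlation and the least-squares line of `method_a` on
#' `method_b`.
#'
#' @inheritParams bland_altman
#' @return List with `r`, `r_squared`, `slope`, `intercept`, `n`.
#' @export
association <- function(method_a, method_b) {
  a <- as.numeric(method_a); b <- as.numeric(method_b)
  if (length(a) != length(b) || length(a) < 3L)
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in one method; association undefined", call. = FALSE)
  r <- stats::cor(a, b)
  fit <- stats::lm(a ~ b)
  list(r = r, r_squared = r^2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(a))
}

#' Descriptive cohort summary by tissue group
#'
#' Per-group mean, SD and n plus pairwise mean differences; a descriptive
#' layer only - no inferential statistics are computed.
#'
#' @param groups Named list mapping group labels to numeric vectors of
#'   per-subject values. Empty groups are reported with `NA`, not dropped.
#' @return List with `summary` (data.frame: `group`, `n`, `mean`, `sd`) and
#'   `differences` (data.frame of pairwise mean differences).
#' @export
cohort_summary <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("`groups` must be a named list", call. = FALSE)
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(group = g, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  nms <- names(groups)
  diffs <- if (length(nms) > 1) {
    pairs <- utils::combn(nms, 2)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      g1 <- pairs[1, i]; g2 <- pairs[2, i]
      m1 <- if (length(groups[[g1]])) mean(groups[[g1]]) else NA_real_
      m2 <- if (length(groups[[g2]])) mean(groups[[g2]]) else NA_real_
      data.frame(group_a = g1, group_b = g2, mean_difference = m1 - m2)
    }))
  } else NULL
  list(summary = summ, differences = diffs)
}
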