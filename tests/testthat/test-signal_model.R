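test_that("parameter constructors enforce their domains", {
  expect_error(acq_params(tr = -1), "tr")
  expect_error(acq_params(te = 4, tr = 3.2), "te")
  expect_error(acq_params(flip_angle = 0), "flip_angle")
  expect_error(acq_params(flip_angle = 120), "flip_angle")
  expect_error(acq_params(rf_duration = 5, tr = 3.2), "rf_duration")
  expect_error(tissue_params(t1 = 40, t2 = 46), "t1 >= t2")
  expect_error(tissue_params(950, 46, bound_fraction = 1), "bound_fraction")
  expect_error(tissue_params(950, 46, exchange_rate = -1), "exchange_rate")
  expect_error(bssfp_signal_single_pool(list(), tissue_params(950, 46)),
               "acq_params")
})

test_that("single-pool signal matches direct evaluation of the closed form", {
  # hand evaluation at the scanner settings (TR 3.2 / TE 1.2 ms, 45 deg)
  e1 <- exp(-3.2 / 950); e2 <- exp(-3.2 / 46)
  expected <- sin(pi / 4) * (1 - e1) /
    (1 - (e1 - e2) * cos(pi / 4) - e1 * e2) * exp(-1.2 / 46)
  got <- bssfp_signal_single_pool(acq_params(3.2, 1.2, 45, 0.3),
                                  tissue_params(950, 46))
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(round(got, 7), 0.0919386)
})

test_that("signal vanishes in the zero-excitation limit and stays in (0, m0]", {
  tis <- tissue_params(950, 46, m0 = 2)
  s_small <- bssfp_signal_single_pool(acq_params(flip_angle = 1e-4), tis)
  expect_lt(s_small, 1e-5)
  for (a in c(5, 20, 45, 70, 90)) {
    s <- bssfp_signal_single_pool(acq_params(flip_angle = a), tis)
    expect_gt(s, 0)
    expect_lte(s, tis$m0)
  }
})

test_that("optimal-angle signal approaches m0/2 * sqrt(T2/T1) at short TR", {
  # numeric maximization over alpha as the oracle
  for (p in list(c(t1 = 1000, t2 = 100), c(t1 = 1200, t2 = 50))) {
    acq_at <- function(a) acq_params(tr = 1, te = 0.5, flip_angle = a,
                                     rf_duration = 0.2)
    tis <- tissue_params(p[["t1"]], p[["t2"]])
    opt <- optimize(function(a) bssfp_signal_single_pool(acq_at(a), tis),
                    c(0.5, 90), maximum = TRUE)
    limit <- 0.5 * sqrt(p[["t2"]] / p[["t1"]])
    expect_equal(opt$objective, limit, tolerance = 0.02)
    cos_star <- (p[["t1"]] / p[["t2"]] - 1) / (p[["t1"]] / p[["t2"]] + 1)
    expect_equal(cos(opt$maximum * pi / 180), cos_star, tolerance = 0.02)
  }
})

test_that("two-pool model reduces to the single pool when F = 0", {
  set.seed(11)
  grid <- expand.grid(alpha = c(5, 15, 30, 45, 60, 90),
                      t1 = c(300, 600, 950, 1200, 1600),
                      t2 = c(30, 46, 60, 120, 250))
  grid <- grid[grid$t1 >= grid$t2, ]
  expect_gte(nrow(grid), 100)
  for (i in seq_len(nrow(grid))) {
    acq <- acq_params(flip_angle = grid$alpha[i])
    tis <- tissue_params(grid$t1[i], grid$t2[i])
    s1 <- bssfp_signal_single_pool(acq, tis)
    s2 <- bssfp_signal_two_pool(acq, tis)
    expect_lt(abs(s2 - s1) / s1, 1e-6)
  }
})

test_that("MT attenuation is monotone in bound fraction and grows with angle", {
  fs <- seq(0, 0.2, by = 0.02)
  for (a in c(5, 45)) {
    acq <- acq_params(flip_angle = a)
    sig <- vapply(fs, function(f)
      bssfp_signal_two_pool(acq, tissue_params(950, 46, bound_fraction = f,
                                               exchange_rate = 4.5)),
      numeric(1))
    expect_true(all(diff(sig) < 0))
    expect_true(all(sig > 0 & sig <= 1))
  }
  # relative attenuation at 5 deg is milder than at 45 deg (W ~ alpha^2)
  att <- function(a) {
    acq <- acq_params(flip_angle = a)
    bssfp_signal_two_pool(acq, remote_tissue()) /
      bssfp_signal_single_pool(acq, remote_tissue())
  }
  expect_gt(att(5), att(45))
  expect_lt(abs(att(5) - 1), abs(att(45) - 1))
})

test_that("delta_s_predicted reflects the contrast mechanism", {
  a5 <- default_acq5(); a45 <- default_acq45()
  expect_error(delta_s_predicted(a45, a5, remote_tissue()), "smaller")

  # lesion-like tissue (longer T2, lower bound fraction) exceeds remote
  expect_gt(delta_s_predicted(a5, a45, lesion_tissue()),
            delta_s_predicted(a5, a45, remote_tissue()))

  # increasing T1 alone decreases delta-S/S0
  ds_t1 <- vapply(seq(800, 1400, by = 100), function(t1)
    delta_s_predicted(a5, a45, tissue_params(t1, 46, bound_fraction = 0.12,
                                             exchange_rate = 4.5)),
    numeric(1))
  expect_true(all(diff(ds_t1) < 0))

  # increasing T2 alone increases delta-S/S0
  ds_t2 <- vapply(seq(40, 80, by = 10), function(t2)
    delta_s_predicted(a5, a45, tissue_params(950, t2, bound_fraction = 0.12,
                                             exchange_rate = 4.5)),
    numeric(1))
  expect_true(all(diff(ds_t2) > 0))

  # decreasing bound fraction increases delta-S/S0
  ds_f <- vapply(seq(0, 0.2, by = 0.04), function(f)
    delta_s_predicted(a5, a45, tissue_params(950, 46, bound_fraction = f,
                                             exchange_rate = 4.5)),
    numeric(1))
  expect_true(all(diff(ds_f) < 0))
})

test_that("sweep driver returns a tidy grid and writes CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  out <- bssfp_sweep(flip_angles = c(5, 45), t1 = c(950, 1200), t2 = 46,
                     bound_fraction = c(0, 0.12), file = f)
  expect_named(out, c("flip_angle_deg", "t1_ms", "t2_ms", "bound_fraction",
                      "signal", "delta_s_pct"))
  expect_equal(nrow(out), 8)
  expect_true(all(is.na(out$delta_s_pct[out$flip_angle_deg == 5])))
  expect_true(all(is.finite(out$delta_s_pct[out$flip_angle_deg == 45])))
  reread <- read.csv(f)
  expect_equal(reread$signal, out$signal, tolerance = 1e-12)
})
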