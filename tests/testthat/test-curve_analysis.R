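mk_ts <- function(l2, dt = 1 / 6) {
  data.frame(time_h = (seq_along(l2) - 1) * dt, count = 2^l2)
}

test_that("local polynomial smoothing reproduces polynomials exactly", {
  t <- (0:144) / 6
  # straight line in log2
  ts <- mk_ts(10 + 0.8 * t)
  sc <- smooth_curve(ts)
  expect_equal(sc$s, 10 + 0.8 * t, tolerance = 1e-9)
  expect_equal(sc$d, rep(0.8 / 6, 144), tolerance = 1e-9)
  # quadratic with degree-2 window: exact everywhere (weighted fit of a
  # quadratic to quadratic data)
  ts2 <- mk_ts(10 + 0.05 * t + 0.01 * t^2)
  sc2 <- smooth_curve(ts2, curve_config(window = 5))
  expect_equal(sc2$s, 10 + 0.05 * t + 0.01 * t^2, tolerance = 1e-8)
})

test_that("smoothing reduces noise on a constant curve", {
  set.seed(31)
  noise <- rnorm(145, 0, 0.05)
  ts <- mk_ts(12 + noise)
  sc <- smooth_curve(ts)
  expect_lt(sd(sc$s - 12), sd(noise))
  expect_error(smooth_curve(data.frame(time_h = 1:5, count = rep(1, 5))),
               "too short")
})

test_that("flat phase follows the derivative band rule", {
  # constant curve: flat phase spans the whole series
  sc <- smooth_curve(mk_ts(rep(10, 60)))
  flat <- find_flat_phase(sc)
  expect_equal(flat$start, 1L)
  expect_equal(flat$end, 61L)
  expect_equal(flat$level, 10)
  # everywhere-steep curve: no flat phase (d = 0.05 per interval)
  sc2 <- smooth_curve(mk_ts(10 + 0.05 * (0:59)))
  expect_null(find_flat_phase(sc2))
  # flat then linear: flat segment ends at the corner (within one index)
  t <- (0:144) / 6
  l2 <- pmin(10 + pmax(0, t - 5), 30)
  sc3 <- smooth_curve(mk_ts(l2))
  flat3 <- find_flat_phase(sc3)
  # brute-force oracle: first index whose derivative leaves the band
  d_ok <- sc3$d > -0.02 & sc3$d < 0.02
  oracle_end <- which.min(d_ok)  # first FALSE
  expect_lte(abs((flat3$end - 1L) - oracle_end), 1L)
  expect_lte(abs((flat3$end - 1) - 31), 4)  # near t = 5 h given smoothing
  # a late plateau does not qualify as the initial flat phase
  l2_late <- c(10 + 0.3 * (0:59), rep(28, 60))
  sc4 <- smooth_curve(mk_ts(l2_late))
  expect_null(find_flat_phase(sc4))
})

test_that("linear phase finds the steepest sustained segment", {
  t <- (0:144) / 6
  l2 <- pmin(10 + pmax(0, t - 5) * 1.0, 26)
  sc <- smooth_curve(mk_ts(l2))
  flat <- find_flat_phase(sc)
  lin <- find_linear_phase(sc, flat)
  expect_equal(lin$slope, 1.0, tolerance = 1e-3)
  expect_gte(lin$start, flat$end)
  # constant curve: absent
  expect_null(find_linear_phase(smooth_curve(mk_ts(rep(10, 60)))))
  # two linear regions: the steeper is selected (brute-force argmax check)
  l2_two <- 10 + cumsum(c(0, rep(0.3 / 6, 60), rep(1.0 / 6, 60)))
  sc2 <- smooth_curve(mk_ts(l2_two))
  lin2 <- find_linear_phase(sc2)
  expect_equal(lin2$slope, 1.0, tolerance = 0.02)
  expect_gt(lin2$start, 55)  # inside the second region
})

test_that("lag is the flat/linear intercept and flags cover the edge cases", {
  # analytic construction: flat at 10 until 5 h then slope 1 =>
  # intercept b solves 10 = 1 * 5 + b
  ts <- simulate_curve(growth_params(lag_h = 5, rate = 1, n0 = 2^10,
                                     capacity = 2^20))
  f <- extract_features(ts)
  expect_equal(f$lag_h, 5, tolerance = 1 / 6)
  expect_equal(f$lag_flag, "measured")
  expect_equal(f$rate, 1, tolerance = 0.02)
  # constant curve: no growth, never a finite lag
  f2 <- extract_features(simulate_curve(growth_params(n0 = 2^14,
                                                      capacity = 2^14,
                                                      lag_h = 3, rate = 1)))
  expect_equal(f2$lag_flag, "no_growth")
  expect_true(is.na(f2$lag_h))
  # growth from t = 0: no detectable lag
  f3 <- extract_features(simulate_curve(growth_params(lag_h = 0, rate = 1)))
  expect_equal(f3$lag_flag, "no_lag")
  expect_equal(f3$lag_h, 0)
})

test_that("lag recovery is exact to one sampling interval on a lag x rate grid", {
  errs <- c()
  for (lag in 1:12) for (rate in c(0.5, 1, 2)) {
    f <- extract_features(simulate_curve(growth_params(lag_h = lag,
                                                       rate = rate)))
    expect_equal(f$lag_flag, "measured",
                 label = sprintf("lag %d rate %.1f", lag, rate))
    errs <- c(errs, abs(f$lag_h - lag))
  }
  expect_equal(sum(errs <= 1 / 6), 36L)
  # rate recovery within 2%
  for (rate in c(0.5, 1, 2)) {
    f <- extract_features(simulate_curve(growth_params(lag_h = 4,
                                                       rate = rate)))
    expect_lt(abs(f$rate - rate) / rate, 0.02)
  }
})

test_that("delaying a curve shifts the extracted lag by the same amount", {
  ts0 <- simulate_curve(growth_params(lag_h = 4, rate = 1))
  f0 <- extract_features(ts0)
  for (k in c(3, 6, 12)) {
    ts1 <- ts0
    ts1$count <- c(rep(ts0$count[1], k),
                   ts0$count[1:(nrow(ts0) - k)])
    f1 <- extract_features(ts1)
    expect_equal(f1$lag_h - f0$lag_h, k / 6, tolerance = 0.01)
  }
})

test_that("lag extraction stays accurate under measurement noise", {
  set.seed(42)
  errs <- numeric(500)
  for (i in 1:500) {
    lag <- runif(1, 2, 10); rate <- runif(1, 0.8, 2)
    f <- extract_features(simulate_curve(
      growth_params(lag_h = lag, rate = rate),
      noise = noise_model(sd_log2 = 0.1), seed = i))
    errs[i] <- if (f$lag_flag == "measured") f$lag_h - lag else -lag
  }
  expect_lte(sqrt(mean(errs^2)), 3 / 6)  # RMSE within three intervals
})

test_that("lag extraction tolerates rounded phase transitions", {
  for (lag in c(3, 6, 9)) {
    f <- extract_features(simulate_curve(growth_params(lag_h = lag, rate = 1),
                                         smooth_span_h = 1))
    expect_equal(f$lag_h, lag, tolerance = 0.35)
  }
})

test_that("QC distinguishes mispinning, artifacts and clean curves", {
  expect_equal(qc_curve(mk_ts(rep(0, 60))), "mispinned")
  expect_equal(qc_curve(simulate_curve(growth_params(lag_h = 5))), "pass")
  # mid-series 3-log2 drop
  l2 <- c(rep(14, 40), rep(11, 40))
  expect_equal(qc_curve(mk_ts(l2)), "rejected")
  # features propagate the qc flag without inventing a lag
  f <- extract_features(mk_ts(l2))
  expect_equal(f$qc, "rejected")
  expect_true(is.na(f$lag_h))
})

test_that("feature tables cover whole plates and survive disk round-trip", {
  ms <- mini_screen()
  truth <- screen_truth(ms$strains, effect = rep(c(0, 1), 6))
  sim <- simulate_plate(ms$layout, truth, seed = 12)
  feats <- extract_features_table(sim$data)
  expect_equal(nrow(feats), 96L)
  grown <- sim$positions[sim$positions$grows, ]
  m <- merge(feats, grown, by = c("row", "col"))
  expect_true(all(m$qc == "pass"))
  expect_equal(m$lag_h, m$true_lag_h, tolerance = 0.2)
  cfg <- curve_config()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_features(feats, path, cfg)
  back <- read_features(path)
  expect_equal(back$lag_h, feats$lag_h, tolerance = 1e-6)
  # config header is echoed
  expect_true(any(grepl("^# window: 9", readLines(path))))
})

test_that("curve config round-trips through YAML", {
  cfg <- curve_config(window = 11, min_slope = 0.08)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_curve_config(cfg, path)
  expect_equal(read_curve_config(path), cfg)
})
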