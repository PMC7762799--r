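test_that("local reference is the median of the k nearest valid controls", {
  lay <- build_screen_layout(list(K1 = sprintf("s%02d", 1:96)))
  ctl_pos <- lay$positions[lay$positions$role == "control_mating", ]
  # all controls at 5 h: reference 5 everywhere
  ctl <- data.frame(row = ctl_pos$row, col = ctl_pos$col, lag_h = 5)
  expect_equal(local_reference(lay, ctl, c(0, 0)), 5)
  expect_equal(local_reference(lay, ctl, c(17, 30)), 5)
  # nearest four {4, 5, 5, 6} -> median 5
  ctl2 <- ctl
  near <- nearest_controls(lay, c(0, 0), 4)
  idx <- match(paste(near$row, near$col), paste(ctl2$row, ctl2$col))
  ctl2$lag_h[idx] <- c(4, 5, 5, 6)
  ctl2$lag_h[-idx] <- 50
  expect_equal(local_reference(lay, ctl2, c(0, 0)), 5)
  expect_error(local_reference(lay, ctl[1:3, ], c(0, 0)), "controls")
})

test_that("normalized effects are log2 lag ratios", {
  expect_equal(normalize_effect(5, 5), 0)
  expect_equal(normalize_effect(10, 5), 1)
  expect_equal(normalize_effect(2.5, 5), -1)
  expect_error(normalize_effect(0, 5), "positive")
  expect_error(normalize_effect(5, 0), "positive")
})

test_that("censoring assigns exactly 2 to no-growth and never caps measured effects", {
  eff <- data.frame(e = c(0.5, NA, 3), status = c("ok", "no_growth", "ok"))
  out <- apply_censoring(eff)
  expect_equal(out$e, c(0.5, 2, 3))
  expect_equal(out$censored, c(FALSE, TRUE, FALSE))
  # boundary consistency: a finite 4x lag gives e = 2 uncensored
  expect_equal(normalize_effect(4 * 5, 5), 2)
  expect_equal(normalize_effect(8 * 5, 5), 3)
})

test_that("plate normalization cancels a smooth spatial field", {
  lay <- build_screen_layout(list(K1 = sprintf("s%02d", 1:96),
                                  K2 = sprintf("t%02d", 1:96)))
  truth <- screen_truth(c(sprintf("s%02d", 1:96), sprintf("t%02d", 1:96)))
  fld <- spatial_field(lay$format, cv_lag = 0.09, seed = 21)
  # noise-free null plate with field: effects vanish up to the field's
  # local curvature
  lags <- simulate_plate_lags(lay, truth, field = fld, sd_log2 = 0, seed = 1)
  norm <- normalize_plate(lags, lay)
  e_exp <- norm$e[norm$role == "experimental_mating"]
  expect_lt(max(abs(e_exp)), 0.05)
  expect_lt(sd(e_exp), 0.02)
  # with replicate noise, the field changes the effect spread by < 10%
  lags_f <- simulate_plate_lags(lay, truth, field = fld, sd_log2 = 0.05,
                                seed = 2)
  lags_0 <- simulate_plate_lags(lay, truth, field = NULL, sd_log2 = 0.05,
                                seed = 2)
  sd_f <- sd(normalize_plate(lags_f, lay)$e[lags_f$role == "experimental_mating"],
             na.rm = TRUE)
  sd_0 <- sd(normalize_plate(lags_0, lay)$e[lags_0$role == "experimental_mating"],
             na.rm = TRUE)
  expect_lt(abs(sd_f / sd_0 - 1), 0.1)
  # local references track the generator's field within 5%
  ctl_lag <- mean(lags$lag_h[lags$role == "control_mating"], na.rm = TRUE)
  ref <- norm$reference
  true_local <- 5.46 * fld$lag_factor[cbind(norm$row + 1, norm$col + 1)]
  expect_lt(max(abs(ref / true_local - 1)), 0.05)
})

test_that("controls normalize against neighbours, not themselves", {
  lay <- build_screen_layout(list(K1 = sprintf("s%02d", 1:96)))
  truth <- screen_truth(sprintf("s%02d", 1:96))
  lags <- simulate_plate_lags(lay, truth, sd_log2 = 0.05, seed = 3)
  norm <- normalize_plate(lags, lay)
  ctl <- norm[norm$role == "control_mating", ]
  expect_true(all(is.finite(ctl$e)))
  expect_lt(abs(mean(ctl$e)), 0.02)
  # a control with an extreme lag does not drag its own reference
  i <- which(lags$role == "control_mating")[1]
  lags$lag_h[i] <- lags$lag_h[i] * 10
  norm2 <- normalize_plate(lags, lay)
  j <- which(norm2$row == lags$row[i] & norm2$col == lags$col[i])
  expect_lt(norm2$reference[j], 2 * 5.46)
})

test_that("Wilcoxon p-values match exhaustive sign-flip enumeration", {
  set.seed(9)
  for (i in 1:60) {
    n <- sample(3:10, 1)
    x <- round(rnorm(n), 3)
    while (any(x == 0) || anyDuplicated(abs(x)) > 0) x <- round(rnorm(n), 3)
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(wilcoxon_signed_rank(x, alternative = alt)$p.value,
                   enum_signrank_p(x, alt), tolerance = 1e-12)
    }
  }
  # with zeros: Pratt enumeration
  for (i in 1:20) {
    n <- sample(4:9, 1)
    x <- round(rnorm(n), 2)
    x[sample(n, sample(1:2, 1))] <- 0
    if (anyDuplicated(abs(x[x != 0])) > 0) next
    expect_equal(wilcoxon_signed_rank(x)$p.value, enum_signrank_p(x),
                 tolerance = 1e-12)
  }
  # known closed forms
  expect_equal(wilcoxon_signed_rank((1:8) / 10)$p.value, 2 / 2^8)
  expect_equal(wilcoxon_signed_rank((1:8) / 10,
                                    alternative = "greater")$p.value, 1 / 2^8)
  expect_equal(wilcoxon_signed_rank(rep(0, 6))$p.value, 1)
  expect_gt(wilcoxon_signed_rank(c(1, -1, 1, -1, 1, -1))$p.value, 0.5)
})

test_that("Wilcoxon approximation stays close to the exact tail for larger n", {
  set.seed(15)
  for (i in 1:10) {
    x <- rnorm(30, 0.3)
    p_approx <- wilcoxon_signed_rank(x, exact_max = 0)$p.value
    p_exact <- wilcox.test(x, exact = TRUE)$p.value
    expect_equal(p_approx, p_exact, tolerance = 0.05)
  }
})

test_that("strain aggregation ranks by median effect with q >= p", {
  ms <- mini_screen()
  truth <- screen_truth(ms$strains,
                        effect = seq(1, -0.5, length.out = 12))
  lags <- rbind(
    cbind(simulate_plate_lags(ms$layout, truth, sd_log2 = 0.05, seed = 4),
          plate = "p1"),
    cbind(simulate_plate_lags(ms$layout, truth, sd_log2 = 0.05, seed = 5),
          plate = "p2"))
  norm <- do.call(rbind, lapply(split(lags, lags$plate), normalize_plate,
                                layout = ms$layout))
  res <- aggregate_and_test(norm)
  expect_setequal(res$rank, 1:12)
  expect_true(all(res$q >= res$p - 1e-12, na.rm = TRUE))
  expect_equal(res$strain[res$rank == 1], "m01")  # largest true effect
  expect_true(all(res$n == 4))
  # under-replicated strains get flagged, not tested
  res2 <- aggregate_and_test(norm[norm$strain == "m01", ][1:2, ], min_n = 3)
  expect_true(all(is.na(res2$p)))
})

test_that("BH adjustment matches the hand formula", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.037), 0.037)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  m <- length(p)
  hand <- rev(cummin(rev(m * p / seq_len(m))))
  expect_equal(fdr_adjust(p), pmin(1, hand))
})

test_that("enrichment equals direct hypergeometric summation", {
  u <- sprintf("g%02d", 1:20)
  e <- enrichment(u[1:5], u[c(1:3, 6, 7)], u)
  expect_equal(e$overlap, 3)
  expect_equal(e$p.value, brute_hyper_p(3, 5, 5, 20), tolerance = 1e-12)
  # random small universes
  set.seed(33)
  for (i in 1:25) {
    N <- sample(10:50, 1)
    u <- sprintf("s%03d", 1:N)
    hits <- sample(u, sample(2:min(10, N), 1))
    gs <- sample(u, sample(2:min(12, N), 1))
    e <- enrichment(hits, gs, u)
    expect_equal(e$p.value,
                 brute_hyper_p(length(intersect(hits, gs)), length(hits),
                               length(gs), N), tolerance = 1e-12)
  }
  # degenerate tables: zero overlap means "at least 0 overlap", p = 1
  expect_equal(enrichment(u[1:4], u[5:9], u)$p.value, 1)
  expect_equal(enrichment(character(0), u[1:3], u)$p.value, 1)
  expect_equal(enrichment(u, u, u)$p.value, 1)
  expect_error(enrichment("a", "a", character(0)), "empty universe")
})

test_that("concordance matches the analytic variance-ratio expectation", {
  r2 <- numeric(10); pred <- numeric(10)
  for (s in 1:10) {
    scr1 <- simulate_screen(100, 8, effect = 0.5, noise_sd_log2 = 0.1,
                            field_cv_lag = 0, seed = 600 + s)
    scr2 <- simulate_screen(100, 8, effect = scr1$truth$effect,
                            noise_sd_log2 = 0.1, field_cv_lag = 0,
                            seed = 700 + s)
    r1 <- analyze_screen(scr1$plates)$strains
    r2s <- analyze_screen(scr2$plates)$strains
    cc <- concordance(r1, r2s)
    r2[s] <- cc$r_squared
    # oracle: squared correlation implied by the variance decomposition,
    # using the truth to measure each screen's median noise
    v_e <- var(scr1$truth$effect)
    v1 <- var(r1$median_e[match(scr1$truth$strain, r1$strain)] -
              scr1$truth$effect)
    v2 <- var(r2s$median_e[match(scr2$truth$strain, r2s$strain)] -
              scr2$truth$effect)
    pred[s] <- v_e / sqrt((v_e + v1) * (v_e + v2))
  }
  expect_lt(abs(mean(r2) - mean(pred^2)), 0.1)
  # trivial anchors
  d <- data.frame(strain = letters[1:5], median_e = c(1, 2, 3, 4, 5))
  d2 <- d; d2$median_e <- -d$median_e
  expect_equal(concordance(d, d)$r_squared, 1)
  expect_equal(concordance(d, d2)$r_squared, 1)
  expect_lt(concordance(d, d2)$slope, 0)
  dz <- d; dz$median_e <- 1
  expect_equal(concordance(d, dz)$flag, "zero_variance")
})

test_that("rate and lag are uncorrelated when simulated independently", {
  set.seed(77)
  rates <- data.frame(strain = sprintf("s%d", 1:500),
                      median_e = rnorm(500, 0, 0.2))
  lags <- data.frame(strain = sprintf("s%d", 1:500),
                     median_e = rnorm(500, 0, 0.3))
  chk <- rate_lag_check(rates, lags)
  expect_lt(chk$r_squared, 0.05)
  same <- rate_lag_check(rates, rates)
  expect_equal(same$r_squared, 1)
  const <- rates; const$median_e <- 0.1
  expect_equal(rate_lag_check(const, lags)$flag, "zero_variance")
})

test_that("screen summary reports mu, sigma, control CV and normal QQ", {
  set.seed(88)
  eff <- rnorm(4000, 0, 0.2)
  sm <- screen_summary(eff, control_lags = rep(5.46, 100))
  expect_lt(abs(sm$mu), 0.01)
  expect_gt(sm$sigma, 0.19); expect_lt(sm$sigma, 0.21)
  expect_equal(sm$cv, 0)
  expect_false(is.unsorted(sm$qq$expected))
  expect_false(is.unsorted(sm$qq$observed))
  # a normal sample stays near the diagonal away from the extreme tails
  inner <- seq(40, 3960)
  expect_lt(max(abs(sm$qq$observed[inner] - sm$qq$expected[inner])), 0.05)
  expect_error(screen_summary(rnorm(5)), ">= 10")
})

test_that("null screens are calibrated: effects centre at zero without false hits", {
  scr <- simulate_screen(500, 8, effect = 0, seed = 11)
  res <- analyze_screen(scr$plates)
  expect_lt(abs(mean(res$strains$median_e)), 0.02)
  expect_lte(mean(res$strains$q < 0.05, na.rm = TRUE), 0.05)
  ctl <- res$replicates[res$replicates$role == "control_mating", ]
  expect_lt(abs(mean(ctl$e, na.rm = TRUE)), 0.02)
})

test_that("estimated effects recover the truth with unit slope", {
  scr <- simulate_screen(500, 8, effect = 0.5, noise_sd_log2 = 0.1,
                         seed = 19)
  res <- analyze_screen(scr$plates)
  m <- merge(res$strains, scr$truth, by = "strain")
  fit <- lm(median_e ~ effect, data = m)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
})

test_that("curve-level and lag-level screens agree end to end", {
  ms <- mini_screen(n_strains = 12, reps = 2)
  truth <- screen_truth(ms$strains, effect = rep(c(0, 0.8), 6))
  plates <- list(
    list(layout = ms$layout,
         curves = simulate_plate(ms$layout, truth,
                                 noise = noise_model(sd_log2 = 0.05),
                                 seed = 31)),
    list(layout = ms$layout,
         curves = simulate_plate(ms$layout, truth,
                                 noise = noise_model(sd_log2 = 0.05),
                                 seed = 32)))
  res <- analyze_screen(plates)
  m <- merge(res$strains, truth, by = "strain")
  expect_equal(m$median_e, m$effect, tolerance = 0.15)
})
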