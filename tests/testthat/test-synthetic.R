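sp <- image_spec()
sp64 <- image_spec(64, field_mm = 64 * 3 / 245)

test_that("generated angiograms hit their PD and FAZ targets", {
  g <- generate_angiogram(sp, 33.4, 0.345, seed = 1)
  expect_lte(abs(g$truth$true_pd_pct - 33.4), 0.5)
  expect_true(g$truth$true_pd_pct >= 32.9 && g$truth$true_pd_pct <= 33.9)
  expect_lte(abs(g$truth$true_faz_mm2 - 0.345), sp$scale_mm_per_px^2)
  expect_false(any(g$truth$vessel_mask & g$truth$faz_mask))
})

test_that("truth masks reproduce the truth table by brute-force counting", {
  for (s in 1:3) {
    g <- generate_angiogram(sp64, 20 + 5 * s, 0.05, seed = s)
    n_f <- sum(g$truth$faz_mask)
    n_v <- sum(g$truth$vessel_mask & !g$truth$faz_mask)
    expect_identical(100 * n_v / (length(g$truth$faz_mask) - n_f),
                     g$truth$true_pd_pct)
    expect_identical(n_f * sp64$scale_mm_per_px^2, g$truth$true_faz_mm2)
  }
})

test_that("zero-density target gives an all-background image", {
  g <- generate_angiogram(sp64, 0, 0, seed = 4)
  expect_equal(g$truth$true_pd_pct, 0)
  expect_false(any(g$truth$vessel_mask))
})

test_that("generation is bit-identical under a fixed seed", {
  g1 <- generate_angiogram(sp, 30, 0.3, seed = 77)
  g2 <- generate_angiogram(sp, 30, 0.3, seed = 77)
  expect_identical(g1$image$pixels, g2$image$pixels)
  expect_identical(g1$truth$vessel_mask, g2$truth$vessel_mask)
  g3 <- generate_angiogram(sp, 30, 0.3, seed = 78)
  expect_false(identical(g1$image$pixels, g3$image$pixels))
})

test_that("unreachable targets fail with a named constraint", {
  expect_error(generate_angiogram(sp64, 99.5, 8, seed = 1), "fit")
  expect_error(generate_angiogram(sp, 120, 0.3, seed = 1), "target_pd")
  expect_error(generate_angiogram(sp, 0.05, 0.345, seed = 1), "ring")
})

test_that("degradation achieves requested deltas within tolerance", {
  g <- generate_angiogram(sp, 33.4, 0.345, seed = 10)
  d <- degrade_angiogram(g$truth, -3.0, 0.10, seed = 11)
  expect_lte(abs((d$truth$true_pd_pct - g$truth$true_pd_pct) + 3.0), 0.5)
  expect_lte(abs((d$truth$true_faz_mm2 - g$truth$true_faz_mm2) - 0.10),
             sp$scale_mm_per_px^2)
  # implied rate arithmetic
  d2 <- degrade_angiogram(g$truth, -3.14, 0, seed = 12)
  expect_equal(change_over_time(g$truth$true_pd_pct, d2$truth$true_pd_pct, 1.3),
               -3.14 / 1.3, tolerance = 0.01)
})

test_that("zero deltas leave the truth unchanged", {
  g <- generate_angiogram(sp, 28, 0.4, seed = 13)
  d <- degrade_angiogram(g$truth, 0, 0, seed = 14)
  expect_identical(d$truth$true_pd_pct, g$truth$true_pd_pct)
  expect_identical(d$truth$true_faz_mm2, g$truth$true_faz_mm2)
})

test_that("degradation is monotone: FAZ never shrinks, vessels only pruned", {
  g <- generate_angiogram(sp, 33.4, 0.345, seed = 15)
  d <- degrade_angiogram(g$truth, -3.0, 0.12, seed = 16)
  # positive area delta never removes FAZ pixels
  expect_true(all(d$truth$faz_mask[g$truth$faz_mask]))
  # negative density delta adds no vessel pixels outside the re-formed
  # capillary margin at the FAZ boundary (<= 3 px band)
  margin <- d$truth$faz_mask
  for (k in 1:3) margin <- octarp:::grow4_(margin)
  added <- d$truth$vessel_mask & !g$truth$vessel_mask & !margin
  expect_equal(sum(added), 0L)
})

test_that("excessive pruning requests fail explicitly", {
  g <- generate_angiogram(sp64, 10, 0.02, seed = 17)
  expect_error(degrade_angiogram(g$truth, -9.99, 0, seed = 18), "density|vessel")
})

test_that("choriocapillaris textures hit their mean gray value", {
  cc <- generate_choriocapillaris(sp, 99.5, 0, seed = 1)
  expect_true(all(cc$pixels == 100L))   # nearest representable 8-bit level
  expect_equal(choriocapillaris_mgv(cc), 100)
  cc0 <- generate_choriocapillaris(sp, 0, 0, seed = 1)
  expect_true(all(cc0$pixels == 0L))
  cc128 <- generate_choriocapillaris(sp, 128, 10, seed = 2)
  expect_lte(abs(choriocapillaris_mgv(cc128) - 128), 3 * 10 / 245)
  expect_error(generate_choriocapillaris(sp, 300, 0, seed = 1), "255")
})

test_that("EZ profiles realize the requested plateau width in pixels", {
  p <- generate_ez_profile(1024, 9, band_width_um = 2674.9, seed = 1)
  expect_equal(attr(p, "true_width_px"), 304L)
  flat <- generate_ez_profile(1024, 9, band_width_um = 0, seed = 1)
  expect_equal(max(flat) - min(flat), 0)
  full <- generate_ez_profile(1024, 9, band_width_um = 9000, seed = 1)
  expect_equal(attr(full, "true_width_px"), 1024L)
  expect_true(all(full > 100))          # plateau covers the whole profile
  expect_error(generate_ez_profile(1024, 9, band_width_um = 9500, seed = 1),
               "wider")
})

test_that("cohort truth draws are calibrated to the configured populations", {
  cs <- cohort_spec(n_eyes = 2000, rng_seed = 99)
  tt <- draw_cohort_truth(cs)
  mp <- cs$metrics
  n <- nrow(tt)
  for (j in seq_len(nrow(mp))) {
    m <- mp$metric[j]
    raw <- tt[[paste0(m, "_v1_raw")]]
    se_mean <- mp$baseline_sd[j] / sqrt(n)
    expect_lte(abs(mean(raw) - mp$baseline_mean[j]), 3 * se_mean)
    expect_lte(abs(sd(raw) - mp$baseline_sd[j]), 3 * mp$baseline_sd[j] / sqrt(2 * n))
    rate <- tt[[paste0(m, "_rate")]]
    expect_lte(abs(mean(rate) - mp$rate_mean[j]), 3 * mp$rate_sd[j] / sqrt(n))
  }
  # correlation calibration against the configured matrix (raw draws)
  R <- cs$correlations
  for (pair in list(c("ez_um", "scp_pd"), c("bcva", "scp_faz"), c("scp_pd", "dcp_pd"))) {
    r_emp <- cor(tt[[paste0(pair[1], "_v1_raw")]], tt[[paste0(pair[2], "_v1_raw")]])
    rho <- R[pair[1], pair[2]]
    expect_lte(abs(r_emp - rho), 3 * (1 - rho^2) / sqrt(n))
  }
  expect_true(all(tt$dt_years >= 0.5))
})

test_that("cohort rate draws honor the SEM-times-sqrt(n) dispersion reading", {
  # between-eye SD of rates is the printed SEM scaled by sqrt(28), so the
  # 28-eye mean rate is itself distributed with SD ~ one printed SEM
  cs <- cohort_spec(n_eyes = 28, rng_seed = 5)
  tt <- draw_cohort_truth(cs)
  expect_lte(abs(mean(tt$scp_pd_rate) - (-2.42)), 2 * 0.62)
  expect_lte(abs(sd(tt$scp_pd_rate) - 0.62 * sqrt(28)),
             3 * 0.62 * sqrt(28) / sqrt(2 * 27))
})

test_that("zero-variance cohorts give identical visits", {
  mp <- default_metric_params()
  mp$rate_mean <- 0; mp$rate_sd <- 0
  cs <- cohort_spec(n_eyes = 4, metrics = mp, rng_seed = 3)
  tt <- draw_cohort_truth(cs)
  for (m in mp$metric)
    expect_equal(tt[[paste0(m, "_v2")]], tt[[paste0(m, "_v1")]])
})

test_that("bivariate table-only draws recover the configured correlation", {
  d <- draw_correlated_pair(5000, 0.660, 2674.9, 1766.8, 33.4, 11.1, seed = 8)
  expect_lte(abs(cor(d$x, d$y) - 0.660), 0.02)
  expect_equal(mean(d$x), 2674.9, tolerance = 1766.8 * 3 / sqrt(5000) / 2674.9)
})

test_that("a non-positive-semidefinite correlation matrix is rejected", {
  R <- default_correlations()
  R["ez_um", "bcva"] <- R["bcva", "ez_um"] <- 0.99
  R["ez_um", "scp_pd"] <- R["scp_pd", "ez_um"] <- 0.99
  R["bcva", "scp_pd"] <- R["scp_pd", "bcva"] <- -0.99
  expect_error(cohort_spec(correlations = R), "positive semidefinite")
  expect_error(cohort_spec(n_eyes = 1), "n_eyes")
})
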