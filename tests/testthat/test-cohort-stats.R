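test_that("one-sample t matches closed-form arithmetic", {
  r <- one_sample_t(c(1, 2, 3))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-10)
  expect_equal(r$p, 0.0742, tolerance = 1e-3)

  sym <- one_sample_t(c(-2, -1, 1, 2))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)

  expect_error(one_sample_t(c(5, 5, 5)), "zero variance")
  expect_error(one_sample_t(3), "at least 2")
})

test_that("paired t reduces to a one-sample t on the differences", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    a <- rnorm(n); b <- rnorm(n)
    pt_ <- paired_t(a, b)
    ot <- one_sample_t(a - b)
    expect_equal(pt_$t, ot$t, tolerance = 1e-12)
    expect_equal(pt_$p, ot$p, tolerance = 1e-12)
    expect_equal(pt_$df, ot$df)
  }
  expect_equal(paired_t(c(1, 2, 3), c(0, 0, 0))$t, one_sample_t(c(1, 2, 3))$t)
  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(paired_t(1:3, 1:3), "zero variance")  # a = b
})

test_that("p-values are uniform under the null hypothesis", {
  set.seed(43)
  ps <- replicate(2000, one_sample_t(rnorm(28))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lte(abs(mean(ps < 0.05) - 0.05), 0.02)
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- rnorm(20, 5, 2)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  # orthogonal-by-construction antisymmetric design
  xx <- c(-2, -1, 1, 2)
  yy <- c(1, -1, -1, 1)
  expect_equal(pearson_r(xx, yy)$r, 0, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("r = 0.660 at n = 28 lands in the p < 0.005 class", {
  d <- exact_cor_pair(28, 0.660, seed = 3)
  pr <- pearson_r(d$x, d$y)
  expect_equal(pr$r, 0.660, tolerance = 1e-10)
  expect_equal(pr$df, 26)
  t_exp <- 0.660 * sqrt(26 / (1 - 0.660^2))
  expect_equal(pr$p, 2 * pt(-t_exp, 26), tolerance = 1e-10)
  expect_lt(pr$p, 0.005)
})

test_that("Pearson r is affine-invariant and antisymmetric under negation", {
  set.seed(44)
  x <- rnorm(25); y <- rnorm(25) + 0.5 * x
  r0 <- pearson_r(x, y)$r
  expect_equal(pearson_r(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_r(x, 0.1 * y - 2)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_r(-x, y)$r, -r0, tolerance = 1e-12)
})

test_that("grader merge returns the reliability r and the averaged series", {
  a <- c(10, 12, 14, 15, 18)
  gm <- grader_merge(a, a)
  expect_equal(gm$pearson_r, 1)
  expect_equal(gm$averaged, a)
  gm2 <- grader_merge(a, a + 2)
  expect_equal(gm2$pearson_r, 1, tolerance = 1e-12)
  expect_equal(gm2$averaged, a + 1)
  # attenuation: small grader noise keeps r > 0.99
  set.seed(45)
  base <- rnorm(200, 30, 8)
  noisy <- base + rnorm(200, 0, 0.05 * sd(base))
  expect_gt(grader_merge(base, noisy)$pearson_r, 0.99)
  expect_error(grader_merge(1:3, 1:4), "equal length")
})

test_that("summary tables recover rates, comparisons and correlations", {
  rec <- make_records(n = 12)
  tb <- build_tables(rec)
  expect_setequal(tb$visits$metric,
                  c("scp_pd", "dcp_pd", "scp_faz", "dcp_faz", "cc_mgv", "ez_um", "bcva"))
  i <- which(tb$visits$metric == "scp_pd")
  rate <- (rec$scp_pd_v2 - rec$scp_pd_v1) / rec$dt_years
  expect_equal(tb$visits$rate_mean[i], mean(rate))
  expect_equal(tb$visits$rate_sem[i], sd(rate) / sqrt(12))
  expect_equal(tb$visits$p_rate[i], one_sample_t(rate)$p)
  expect_equal(tb$visits$v1_mean[i], mean(rec$scp_pd_v1))
  expect_true(all(c("PD SCP vs DCP, visit 1", "PD rate SCP vs DCP",
                    "FAZ SCP vs DCP, visit 2") %in% tb$comparisons$comparison))
  expect_equal(nrow(tb$correlations), 2 * 5 * 2)
  j <- which(tb$correlations$functional == "ez_um" &
               tb$correlations$metric == "scp_pd" & tb$correlations$visit == 1)
  expect_equal(tb$correlations$r[j], pearson_r(rec$ez_um_v1, rec$scp_pd_v1)$r)
  expect_identical(tb$correlations$significant, tb$correlations$p < 0.05)
})

test_that("summary tables are a pure function of their input", {
  rec <- make_records(n = 9)
  expect_identical(build_tables(rec), build_tables(rec))
})

test_that("degenerate cohorts surface undefined-variance tests per metric", {
  rec <- make_records(n = 6)
  for (m in c("scp_pd")) rec[[paste0(m, "_v2")]] <- rec[[paste0(m, "_v1")]]
  expect_warning(build_tables(rec), "zero variance")
  tb <- suppressWarnings(build_tables(rec))
  i <- which(tb$visits$metric == "scp_pd")
  expect_true(is.na(tb$visits$p_rate[i]))
  expect_false(anyNA(tb$visits$p_rate[-i]))
})

test_that("missing metrics fall back to complete cases with reported n", {
  rec <- make_records(n = 10)
  rec$cc_mgv_v1[1:4] <- NA
  tb <- suppressWarnings(build_tables(rec))
  i <- which(tb$visits$metric == "cc_mgv")
  expect_equal(tb$visits$n[i], 6)
  expect_equal(tb$visits$n[tb$visits$metric == "scp_pd"], 10)
  # an all-missing metric is dropped with a warning
  rec$dcp_faz_v1[] <- NA
  expect_warning(tb2 <- build_tables(rec), "dropped")
  expect_false("dcp_faz" %in% tb2$visits$metric)
})

test_that("BH adjustment is available but off by default", {
  rec <- make_records(n = 12)
  tb <- build_tables(rec)
  expect_null(tb$correlations$p_bh)
  tb2 <- build_tables(rec, fdr = "bh")
  expect_equal(tb2$correlations$p_bh,
               p.adjust(tb2$correlations$p, method = "BH"))
})
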