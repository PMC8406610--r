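test_that("paired t-test matches the hand-computed formula", {
  # diffs -1,-1,-2,-2: mean -1.5, sd 0.57735, t = -1.5/(sd/2) = -5.196
  res <- paired_t(c(1, 2, 3, 4), c(2, 3, 5, 6))
  expect_equal(res$mean_diff, -1.5)
  expect_equal(res$t, -5.196152, tolerance = 1e-6)
  expect_equal(res$df, 3)
  expect_false(res$degenerate)

  # identical vectors: degenerate, p undefined
  res0 <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_true(res0$degenerate)
  expect_true(is.na(res0$p))
  expect_equal(res0$mean_diff, 0)

  expect_error(paired_t(1:2, 1:2), "n >= 3")
  expect_error(paired_t(1:4, 1:3), "equal length")
})

test_that("independent t-test uses the pooled-variance form", {
  res <- independent_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$mean_diff, -3)
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  res0 <- independent_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$t, 0)
  expect_error(independent_t(1, c(1, 2)), "at least 2")
})

test_that("pooled-SD Cohen's d reproduces worked examples and is well-behaved", {
  expect_equal(cohens_d(0.90, 0.23, 1.39, 0.37)$d, 1.59, tolerance = 0.005)
  expect_equal(cohens_d(1.24, 0.05, 1.16, 0.05)$d, 1.60, tolerance = 0.005)
  expect_equal(cohens_d(1, 0.5, 1, 0.3)$d, 0)
  expect_equal(cohens_d(1, 0.5, 1, 0.3)$band, "trivial")

  # symmetry and scale invariance
  set.seed(1)
  for (i in 1:10) {
    ms <- runif(2, 0, 5); sds <- runif(2, 0.1, 2); cc <- runif(1, 0.1, 10)
    d1 <- cohens_d(ms[1], sds[1], ms[2], sds[2])$d
    d2 <- cohens_d(ms[2], sds[2], ms[1], sds[1])$d
    d3 <- cohens_d(cc * ms[1], cc * sds[1], cc * ms[2], cc * sds[2])$d
    expect_equal(d1, d2, tolerance = 1e-12)
    expect_equal(d1, d3, tolerance = 1e-12)
  }
  expect_error(cohens_d(1, 0, 2, 0), "both SDs are zero")
})

test_that("difference-score d is available for paired data", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 5, 6)
  res <- cohens_d_paired(x, y)
  expect_equal(res$d, 1.5 / sd(x - y), tolerance = 1e-12)
  expect_error(cohens_d_paired(1:3, 2:4), "zero-variance")
})

test_that("interpretation bands follow the published cut-points", {
  expect_equal(d_band(c(0.1, 0.19, 0.2, 0.49, 0.5, 0.79, 0.8, 2)),
               c("trivial", "trivial", "small", "small", "moderate",
                 "moderate", "large", "large"))
  expect_equal(r_band(c(0.05, 0.2, 0.4, 0.6, 0.8, 0.95, -0.95)),
               c("negligible", "minor", "moderate", "large", "very large",
                 "perfect", "perfect"))
})

test_that("correlation handles ranks, bands and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  res <- correlate(x, x, "spearman")
  expect_equal(res$r, 1)
  expect_equal(res$band, "perfect")
  expect_equal(correlate(x, x, "pearson")$r, 1)

  # monotone nonlinear: Spearman 1, Pearson < 1
  y <- exp(x)
  expect_equal(correlate(x, y, "spearman")$r, 1)
  expect_lt(correlate(x, y, "pearson")$r, 1)

  # Spearman equals Pearson on brute-force ranks
  set.seed(4)
  a <- rnorm(9); b <- rnorm(9)
  brute_rank <- function(v) vapply(v, function(vi) sum(v <= vi), numeric(1))
  expect_equal(correlate(a, b, "spearman")$r,
               correlate(brute_rank(a), brute_rank(b), "pearson")$r,
               tolerance = 1e-12)

  expect_error(correlate(rep(1, 5), x), "constant")
})

test_that("simple regression matches the normal equations", {
  x <- c(1, 2, 3, 4, 5)
  res <- simple_regression(x, 2 * x + 1)
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_equal(res$intercept, 1, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)

  set.seed(9)
  xr <- rnorm(5); yr <- rnorm(5)
  res <- simple_regression(xr, yr)
  # closed-form normal equations
  slope <- sum((xr - mean(xr)) * (yr - mean(yr))) / sum((xr - mean(xr))^2)
  expect_equal(res$slope, slope, tolerance = 1e-12)
  expect_equal(res$intercept, mean(yr) - slope * mean(xr), tolerance = 1e-12)
  # line passes through the centroid
  expect_equal(res$slope * mean(xr) + res$intercept, mean(yr),
               tolerance = 1e-9)
  # r^2 consistency with the Pearson correlation
  expect_equal(res$r_squared, correlate(xr, yr, "pearson")$r^2,
               tolerance = 1e-12)

  expect_error(simple_regression(rep(1, 5), x), "constant")
})

test_that("uncorrelated noise gives near-zero r-squared in expectation", {
  set.seed(12)
  r2 <- replicate(200, simple_regression(rnorm(30), rnorm(30))$r_squared)
  expect_lt(mean(r2), 0.07)  # E[r^2] = 1/(n-1) under the null
})

test_that("method-comparison table has the validity-table structure with blank cells", {
  coh <- simulate_cohort(n_per_sex = 5, noise_sd_N = 3, seed = 31)
  vars <- analyze_cohort(coh)
  comp <- build_comparison(vars, "method")
  expect_s3_class(comp, "pushup_comparison")
  expect_equal(nrow(comp), 8)
  # blank comparison rows for variables identical across methods
  blanks <- comp$variable %in% c("peak_hands_grf_BW", "feet_grf_start_BW")
  expect_true(all(is.na(comp$p[blanks])))
  expect_true(all(is.na(comp$d[blanks])))
  expect_true(all(!is.na(comp$p[!blanks])))
  # the dip-driven overestimation shows up as a significant large effect
  pv <- comp[comp$variable == "peak_wholebody_velocity_mps", ]
  expect_lt(pv$mean_a, pv$mean_b)  # two-platform < one-platform
  expect_lt(pv$p, 0.05)
  expect_equal(pv$d_band, "large")
  # regression predictions apply the stored coefficients
  pred <- predict(comp, 1.4, "peak_wholebody_velocity_mps")
  expect_equal(pred, pv$slope * 1.4 + pv$intercept)
})

test_that("comparison with identical methods yields zero effect sizes", {
  coh <- simulate_cohort(n_per_sex = 3, noise_sd_N = 0, seed = 17)
  vars <- analyze_cohort(coh)
  # overwrite one-platform rows with two-platform values
  two <- vars[vars$method == "two_platform", ]
  dup <- two; dup$method <- "one_platform"
  comp <- build_comparison(rbind(two, dup), "method")
  active <- !comp$variable %in% c("peak_hands_grf_BW", "feet_grf_start_BW")
  expect_true(all(comp$d[active] == 0))
  expect_true(all(is.na(comp$p[active])))  # degenerate paired tests
})

test_that("sex comparison reproduces the expected male-female contrasts", {
  coh <- simulate_cohort(n_per_sex = 6, noise_sd_N = 3, seed = 41)
  vars <- analyze_cohort(coh)
  comp <- build_comparison(vars, "sex")
  expect_equal(nrow(comp), 8)
  pk <- comp[comp$variable == "peak_wholebody_velocity_mps", ]
  expect_gt(pk$mean_a, pk$mean_b)  # males push faster
  fs <- comp[comp$variable == "feet_grf_start_BW", ]
  expect_lt(fs$mean_a, fs$mean_b)  # females load the feet more
  expect_error(predict(comp, 1, "peak_wholebody_velocity_mps"),
               "method-grouped")
})

test_that("unbalanced pairing is rejected", {
  coh <- simulate_cohort(n_per_sex = 3, noise_sd_N = 0, seed = 19)
  vars <- analyze_cohort(coh)
  vars <- vars[!(vars$participant_id == "P01" &
                   vars$method == "one_platform"), ]
  expect_error(build_comparison(vars, "method"), "unbalanced pairing")
})
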