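make_phase <- function(start, end, fs = 1000) {
  structure(list(start_index = start, end_index = end,
                 start_time_s = (start - 1) / fs,
                 end_time_s = (end - 2) / fs),
            class = "pushup_phase")
}

test_that("total-force construction follows each method's definition", {
  fs <- 1000
  rec <- pushup_recording(force_trace(c(450, 400, 300), fs, "hands"),
                          force_trace(c(235, 200, 250), fs, "feet"))
  ph <- make_phase(2L, 4L)
  expect_equal(total_force_two_platform(rec, ph), c(600, 550))
  b <- make_baseline(hands_static = 450, feet_static = 238)
  expect_equal(total_force_one_platform(rec, ph, b), c(638, 538))

  rec1 <- pushup_recording(force_trace(c(450, 400, 300), fs, "hands"),
                           body_mass = 70)
  expect_error(total_force_two_platform(rec1, ph), "method unavailable")
  expect_error(total_force_one_platform(rec, make_phase(2L, 2L), b),
               "degenerate phase")
})

test_that("impulse-momentum velocity satisfies closed-form oracles", {
  cfg <- pushup_config()
  m <- 70
  fs <- 1000
  # zero net force -> zero velocity
  v <- impulse_velocity(rep(m * cfg$gravity, 500), m, cfg, fs)
  expect_equal(v, rep(0, 500), tolerance = 1e-12)
  expect_identical(v[1], 0)

  # constant net force of 70 N on 70 kg for 1 s -> exactly 1 m/s
  v <- impulse_velocity(rep(m * cfg$gravity + 70, 1001), m, cfg, fs)
  expect_equal(v[1001], 1, tolerance = 1e-9)

  # sinusoidal acceleration: v(t) = (A/omega)(1 - cos(omega t))
  A <- 3; omega <- 2 * pi
  tt <- seq(0, 1, by = 1 / fs)
  f <- m * (cfg$gravity + A * sin(omega * tt))
  v <- impulse_velocity(f, m, cfg, fs)
  v_exact <- (A / omega) * (1 - cos(omega * tt))
  expect_lt(max(abs(v - v_exact)), 1e-4)

  expect_error(impulse_velocity(c(1, NA, 3), m, cfg, fs), "non-finite")
})

test_that("trapezoidal velocity error shrinks ~4x when the step halves", {
  cfg <- pushup_config()
  m <- 70; A <- 4; Tlobe <- 0.6
  err_at <- function(fs) {
    tt <- seq(0, Tlobe, by = 1 / fs)
    a <- A / 2 * (1 - cos(2 * pi * tt / Tlobe))
    v_exact <- A / 2 * (tt - Tlobe / (2 * pi) * sin(2 * pi * tt / Tlobe))
    v <- impulse_velocity(m * (cfg$gravity + a), m, cfg, fs)
    max(abs(v - v_exact))
  }
  e1 <- err_at(500); e2 <- err_at(1000)
  expect_lt(e2, 1e-4)
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 5)
})

test_that("power is the elementwise force-velocity product", {
  expect_equal(power_series(c(700, 650), c(0, 0)), c(0, 0))
  expect_equal(power_series(700, 1), 700)
  expect_error(power_series(c(1, 2), c(1, 2, 3)), "equal length")

  sim <- simulate_trial(sim_params(noise_sd_N = 0))
  fit <- analyze_trial(sim$recording)
  for (m in names(fit$methods)) {
    r <- fit$methods[[m]]
    expect_equal(r$power, r$total_force * r$velocity, tolerance = 1e-12)
  }
})

test_that("impulse-difference identity links the two methods exactly", {
  cfg <- pushup_config()
  set.seed(7)
  for (rep in 1:5) {
    n <- 400
    fs <- 1000
    m <- runif(1, 50, 95)
    hands <- 450 + cumsum(rnorm(n, 0, 2))
    feet <- 230 + cumsum(rnorm(n, 0, 2))
    feet_static <- 230
    v_two <- impulse_velocity(hands + feet, m, cfg, fs)
    v_one <- impulse_velocity(hands + feet_static, m, cfg, fs)
    lhs <- v_one - v_two
    rhs <- as.numeric(pracma::cumtrapz(feet_static - feet)) / (m * fs)
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("BW-normalized variables are invariant to mass-force rescaling", {
  # the pipeline is homogeneous of degree zero in (forces, mass, threshold):
  # the 15 N detection threshold is an absolute force, so it scales along
  sim <- simulate_trial(sim_params(noise_sd_N = 0))
  rec <- sim$recording
  fit1 <- analyze_trial(rec)
  for (c_scale in c(0.5, 2)) {
    rec2 <- rec
    rec2$hands$samples <- rec$hands$samples * c_scale
    rec2$feet$samples <- rec$feet$samples * c_scale
    rec2$body_mass <- rec$body_mass * c_scale
    fit2 <- analyze_trial(rec2, pushup_config(phase_threshold = 15 * c_scale))
    v1 <- coef(fit1); v2 <- coef(fit2)
    bw_vars <- grep("_BW$", colnames(v1), value = TRUE)
    expect_equal(v2[, bw_vars], v1[, bw_vars], tolerance = 1e-9)
  }
})

test_that("peak-power ties resolve to the first occurrence", {
  rec <- make_constant_feet_recording()
  b <- make_baseline(hands_static = 454)
  ph <- make_phase(2L, 6L)
  force <- c(100, 200, 100, 200)
  vel <- c(2, 1, 2, 1)  # power = 200 200 200 200, tie everywhere
  pow <- power_series(force, vel)
  vars <- extract_variables(rec, ph, b, force, vel, pow,
                            method = "one_platform")
  expect_equal(vars[["wholebody_grf_at_peak_power_BW"]], 100 / b$body_weight)
  expect_equal(vars[["wholebody_velocity_at_peak_power_mps"]], 2)
})

test_that("analyze_trial agrees across methods when the feet force is constant", {
  fit <- analyze_trial(make_constant_feet_recording())
  two <- fit$methods$two_platform
  one <- fit$methods$one_platform
  expect_lt(max(abs(one$velocity - two$velocity)), 1e-6)
  expect_lt(max(abs(one$power - two$power)) / max(abs(two$power)), 1e-6)
  # hands-derived and start variables are identical across methods
  expect_identical(coef(fit)["two_platform", "peak_hands_grf_BW"],
                   coef(fit)["one_platform", "peak_hands_grf_BW"])
  expect_identical(coef(fit)["two_platform", "feet_grf_start_BW"],
                   coef(fit)["one_platform", "feet_grf_start_BW"])
  # one-platform mean feet force equals its start value exactly
  expect_identical(coef(fit)["one_platform", "mean_feet_grf_BW"],
                   coef(fit)["one_platform", "feet_grf_start_BW"])
})

test_that("one-platform acquisition yields a flagged one-method fit", {
  sim <- simulate_trial(sim_params(noise_sd_N = 0))
  rec <- sim$recording
  rec1 <- pushup_recording(rec$hands, feet = NULL, body_mass = rec$body_mass)
  fit <- analyze_trial(rec1)
  expect_true(fit$one_platform_only)
  expect_named(fit$methods, "one_platform")
  expect_error(analyze_trial(rec1, methods = "two_platform"),
               "no feet trace")
})
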