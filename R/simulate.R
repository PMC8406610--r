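#' Parameters of the mechanistic push-up simulator
#'
#' Defines a piecewise-smooth center-of-mass (COM) acceleration profile and a
#' feet-force share function from which paired hands/feet GRF traces are
#' constructed. The movement is: a quiet static hold; a raised-cosine descent
#' (countermovement) lobe with peak `descent_peak_accel`; a raised-cosine
#' propulsive lobe with peak `push_peak_accel`; and a smoothstep takeoff tail
#' during which the COM acceleration drops toward `-tail_drop_g * g` as the
#' hands unload. The feet share of total force starts at `static_feet_share`,
#' dips by `feet_dip_depth` during the descent (COM shifting forward onto the
#' hands), holds the dip through the push, and rises to `feet_end_share`
#' during the tail (COM rocking back over the feet), driving the hands force
#' below the takeoff threshold.
#'
#' @param body_mass Body mass (kg).
#' @param static_feet_share Fraction of body weight on the feet during the
#'   static hold, in (0, 1).
#' @param quiet_duration_s Duration of the static hold (s).
#' @param descent_duration_s,push_duration_s Durations of the two
#'   acceleration lobes (s).
#' @param descent_peak_accel Peak descent acceleration (m/s^2, negative).
#' @param push_peak_accel Peak propulsive acceleration (m/s^2, positive).
#' @param feet_dip_depth How far the feet share drops below its static value
#'   during descent/push (share units).
#' @param feet_end_share Feet share approached near hand takeoff (close to 1).
#' @param tail_drop_g Magnitude of the COM deceleration reached at the end of
#'   the takeoff tail, as a fraction of g.
#' @param tail_duration_s Duration of the takeoff tail (s).
#' @param noise_sd_N SD of additive white Gaussian sensor noise per platform
#'   (N); 0 for a noiseless trial.
#' @param seed Optional integer seed for the noise stream.
#'
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(body_mass = 70.2,
                       static_feet_share = 0.34,
                       quiet_duration_s = 1.0,
                       descent_duration_s = 0.40,
                       push_duration_s = 0.70,
                       descent_peak_accel = -3.0,
                       push_peak_accel = 4.3,
                       feet_dip_depth = 0.08,
                       feet_end_share = 0.90,
                       tail_drop_g = 0.90,
                       tail_duration_s = 0.12,
                       noise_sd_N = 0,
                       seed = NULL) {
  p <- list(body_mass = body_mass, static_feet_share = static_feet_share,
            quiet_duration_s = quiet_duration_s,
            descent_duration_s = descent_duration_s,
            push_duration_s = push_duration_s,
            descent_peak_accel = descent_peak_accel,
            push_peak_accel = push_peak_accel,
            feet_dip_depth = feet_dip_depth,
            feet_end_share = feet_end_share,
            tail_drop_g = tail_drop_g,
            tail_duration_s = tail_duration_s,
            noise_sd_N = noise_sd_N, seed = seed)
  stopifnot(body_mass > 0,
            static_feet_share > 0, static_feet_share < 1,
            quiet_duration_s > 0, descent_duration_s > 0,
            push_duration_s > 0, tail_duration_s > 0,
            descent_peak_accel < 0, push_peak_accel > 0,
            feet_dip_depth >= 0,
            feet_dip_depth < static_feet_share,
            feet_end_share > 0, feet_end_share <= 1,
            tail_drop_g >= 0, tail_drop_g < 1,
            noise_sd_N >= 0)
  structure(p, class = "sim_params")
}

# cubic smoothstep on [0, 1], clamped outside
smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

# closed-form kinematic and share functions for a parameter set
sim_functions <- function(params, gravity = 9.81) {
  p <- params
  tq <- p$quiet_duration_s
  t1 <- tq + p$descent_duration_s
  t2 <- t1 + p$push_duration_s
  t3 <- t2 + p$tail_duration_s
  Ad <- p$descent_peak_accel  # negative
  Ap <- p$push_peak_accel
  Td <- p$descent_duration_s
  Tp <- p$push_duration_s
  Tt <- p$tail_duration_s
  G <- p$tail_drop_g * gravity
  v1 <- Ad * Td / 2                 # velocity at bottom of descent
  v2 <- v1 + Ap * Tp / 2            # velocity at end of push
  s0 <- p$static_feet_share
  sd_ <- s0 - p$feet_dip_depth      # dipped share
  se <- p$feet_end_share

  accel_fn <- function(t) {
    a <- numeric(length(t))
    i <- t >= tq & t < t1
    a[i] <- Ad / 2 * (1 - cos(2 * pi * (t[i] - tq) / Td))
    i <- t >= t1 & t < t2
    a[i] <- Ap / 2 * (1 - cos(2 * pi * (t[i] - t1) / Tp))
    i <- t >= t2
    a[i] <- -G * smoothstep((t[i] - t2) / Tt)
    a
  }
  velocity_fn <- function(t) {
    v <- numeric(length(t))
    i <- t >= tq & t < t1
    tau <- t[i] - tq
    v[i] <- Ad / 2 * (tau - Td / (2 * pi) * sin(2 * pi * tau / Td))
    i <- t >= t1 & t < t2
    tau <- t[i] - t1
    v[i] <- v1 + Ap / 2 * (tau - Tp / (2 * pi) * sin(2 * pi * tau / Tp))
    i <- t >= t2
    u <- pmin(1, (t[i] - t2) / Tt)
    v[i] <- v2 - G * Tt * (u^3 - u^4 / 2)
    v
  }
  feet_share_fn <- function(t) {
    s <- rep(s0, length(t))
    i <- t >= tq & t < t1
    s[i] <- s0 - p$feet_dip_depth * smoothstep((t[i] - tq) / Td)
    i <- t >= t1 & t < t2
    s[i] <- sd_
    i <- t >= t2
    s[i] <- sd_ + (se - sd_) * smoothstep((t[i] - t2) / Tt)
    s
  }
  total_force_fn <- function(t) p$body_mass * (gravity + accel_fn(t))
  feet_fn <- function(t) feet_share_fn(t) * total_force_fn(t)
  hands_fn <- function(t) (1 - feet_share_fn(t)) * total_force_fn(t)

  list(accel_fn = accel_fn, velocity_fn = velocity_fn,
       feet_share_fn = feet_share_fn, total_force_fn = total_force_fn,
       feet_fn = feet_fn, hands_fn = hands_fn,
       marks = c(quiet_end = tq, descent_end = t1, push_end = t2, end = t3))
}

# first time in [lo, hi] where f(t) drops strictly below `level`;
# grid scan then root refinement
first_crossing_below <- function(f, level, lo, hi, grid_dt = 1e-4) {
  tt <- seq(lo, hi, by = grid_dt)
  y <- f(tt)
  below <- which(y < level)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (i == 1) return(tt[1])
  stats::uniroot(function(t) f(t) - level, lower = tt[i - 1], upper = tt[i],
                 tol = 1e-9)$root
}

#' Simulate one plyometric push-up trial with analytic ground truth
#'
#' Builds synchronized hands/feet GRF traces from the closed-form COM
#' acceleration and feet-share functions of [sim_params()]. Pre-noise, force
#' conservation `F_hands + F_feet = m (g + a)` holds exactly at every sample.
#' The returned ground truth carries the analytic functions, the configured
#' movement start, the root-found onset and takeoff threshold crossings, and
#' the expected outcome variables for both calculation methods computed from
#' the analytic curves on a fine (10x oversampled) grid.
#'
#' @param params A [sim_params()].
#' @param sampling_rate Sampling rate (Hz).
#' @param config A [pushup_config()]; supplies gravity and the 15 N phase
#'   threshold used for the ground-truth onset/takeoff times.
#'
#' @return A list of class `pushup_sim` with elements `recording`
#'   (a [pushup_recording()]) and `ground_truth` (class `pushup_sim_truth`).
#' @examples
#' sim <- simulate_trial(sim_params(noise_sd_N = 0))
#' sim$ground_truth$takeoff_time_s
#' @export
simulate_trial <- function(params = sim_params(), sampling_rate = 1000,
                           config = pushup_config()) {
  stopifnot(inherits(params, "sim_params"))
  config <- as_pushup_config(config)
  g <- config$gravity
  thr <- config$phase_threshold
  fn <- sim_functions(params, g)
  t_end <- fn$marks[["end"]]
  tq <- fn$marks[["quiet_end"]]

  hands_static <- (1 - params$static_feet_share) * params$body_mass * g
  t_off <- first_crossing_below(fn$hands_fn, thr, tq, t_end)
  if (is.na(t_off)) {
    stop("simulation infeasible: hands force never drops below the ",
         thr, " N takeoff threshold", call. = FALSE)
  }
  t_on <- first_crossing_below(fn$hands_fn, hands_static - thr, tq, t_off)
  if (is.na(t_on)) {
    stop("simulation infeasible: hands force never drops ", thr,
         " N below its static value before takeoff", call. = FALSE)
  }

  n <- as.integer(round(t_end * sampling_rate)) + 1L
  tt <- (seq_len(n) - 1) / sampling_rate
  hands <- fn$hands_fn(tt)
  feet <- fn$feet_fn(tt)
  if (params$noise_sd_N > 0) {
    if (!is.null(params$seed)) set.seed(params$seed)
    hands <- hands + stats::rnorm(n, 0, params$noise_sd_N)
    feet <- feet + stats::rnorm(n, 0, params$noise_sd_N)
  }
  recording <- pushup_recording(
    hands = force_trace(hands, sampling_rate, "hands"),
    feet = force_trace(feet, sampling_rate, "feet"),
    body_mass = params$body_mass
  )

  truth <- structure(
    c(fn[c("accel_fn", "velocity_fn", "feet_share_fn", "total_force_fn",
           "feet_fn", "hands_fn")],
      list(movement_start_s = tq,
           onset_time_s = t_on,
           takeoff_time_s = t_off,
           body_weight = params$body_mass * g,
           hands_static = hands_static,
           feet_static = params$static_feet_share * params$body_mass * g,
           params = params,
           expected_variables = sim_expected_variables(params, fn, t_on,
                                                       t_off, g,
                                                       10 * sampling_rate))),
    class = "pushup_sim_truth")
  structure(list(recording = recording, ground_truth = truth),
            class = "pushup_sim")
}

# expected outcome variables for both methods from the analytic curves,
# evaluated on a fine grid over the analytic phase window
sim_expected_variables <- function(params, fn, t_on, t_off, gravity,
                                   fine_rate) {
  m <- params$body_mass
  bw <- m * gravity
  feet_static <- params$static_feet_share * bw
  tt <- seq(t_on, t_off, by = 1 / fine_rate)
  dt <- 1 / fine_rate

  v <- fn$velocity_fn(tt) - fn$velocity_fn(t_on)[1]
  f_two <- fn$total_force_fn(tt)
  feet <- fn$feet_fn(tt)
  hands <- fn$hands_fn(tt)
  p_two <- f_two * v

  f_one <- hands + feet_static
  v_one <- v + as.numeric(pracma::cumtrapz(feet_static - feet)) * dt / m
  p_one <- f_one * v_one

  mk <- function(force, vel, pow, feet_mean) {
    i_pp <- which.max(pow)
    c(peak_hands_grf_BW = max(hands) / bw,
      peak_wholebody_grf_BW = max(force) / bw,
      peak_wholebody_velocity_mps = max(vel),
      peak_wholebody_power_WperBW = max(pow) / bw,
      feet_grf_start_BW = feet_static / bw,
      mean_feet_grf_BW = feet_mean / bw,
      wholebody_grf_at_peak_power_BW = force[i_pp] / bw,
      wholebody_velocity_at_peak_power_mps = vel[i_pp])
  }
  rbind(two_platform = mk(f_two, v, p_two, mean(feet)),
        one_platform = mk(f_one, v_one, p_one, feet_static))
}

#' @export
print.pushup_sim <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<pushup_sim: %.1f kg, onset %.3f s, takeoff %.3f s, noise SD %g N>\n",
              gt$params$body_mass, gt$onset_time_s, gt$takeoff_time_s,
              gt$params$noise_sd_N))
  invisible(x)
}
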