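#' Whole-body force over the phase, two-platform method
#'
#' Element-wise sum of the measured hands and feet forces over the detected
#' push-up phase.
#'
#' @param recording A [pushup_recording()] with both (filtered) traces.
#' @param phase A `pushup_phase`.
#' @return Numeric vector of whole-body force (N), one value per phase sample.
#' @export
total_force_two_platform <- function(recording, phase) {
  if (!has_feet(recording)) {
    stop("method unavailable: no feet trace in this recording", call. = FALSE)
  }
  idx <- phase_indices(phase)
  if (length(idx) == 0) stop("degenerate phase of length 0", call. = FALSE)
  recording$hands$samples[idx] + recording$feet$samples[idx]
}

#' Whole-body force over the phase, one-platform method
#'
#' Hands force over the phase plus a constant feet force equal to its static
#' value, `feet_static = body_weight - hands_static`, i.e. the feet force is
#' assumed to stay at its starting value throughout the push-up.
#'
#' @param recording A [pushup_recording()] with a (filtered) hands trace.
#' @param phase A `pushup_phase`.
#' @param baseline A `pushup_baseline`.
#' @return Numeric vector of whole-body force (N), one value per phase sample.
#' @export
total_force_one_platform <- function(recording, phase, baseline) {
  if (is.null(baseline)) stop("baseline missing", call. = FALSE)
  stopifnot(inherits(baseline, "pushup_baseline"))
  idx <- phase_indices(phase)
  if (length(idx) == 0) stop("degenerate phase of length 0", call. = FALSE)
  recording$hands$samples[idx] + baseline$feet_static
}

#' Impulse-momentum whole-body velocity
#'
#' Integrates the net force `F_total - m g` over time with the cumulative
#' trapezoidal rule and divides by body mass, yielding the whole-body
#' (center-of-mass) vertical velocity from a stationary start:
#' `v(t_k) = (1/m) * integral from phase start to t_k of (F_total - m g)`.
#' `v[1]` is exactly 0.
#'
#' @param total_force Whole-body force series over the phase (N).
#' @param body_mass Body mass in kg.
#' @param config A [pushup_config()] (supplies gravity).
#' @param sampling_rate Sampling rate of the series (Hz).
#' @return Numeric velocity series (m/s, upward positive), same length.
#' @export
impulse_velocity <- function(total_force, body_mass,
                             config = pushup_config(), sampling_rate) {
  config <- as_pushup_config(config)
  if (!all(is.finite(total_force))) {
    stop("non-finite values in the force series", call. = FALSE)
  }
  if (length(total_force) < 2) {
    stop("force series must have at least 2 samples", call. = FALSE)
  }
  if (body_mass <= 0) stop("`body_mass` must be positive", call. = FALSE)
  net <- total_force - body_mass * config$gravity
  dt <- 1 / sampling_rate
  as.numeric(pracma::cumtrapz(net) * dt / body_mass)
}

#' Whole-body power series
#'
#' Element-wise product of the whole-body force and velocity series.
#'
#' @param total_force Force series (N).
#' @param velocity Velocity series (m/s).
#' @return Power series (W).
#' @export
power_series <- function(total_force, velocity) {
  if (length(total_force) != length(velocity)) {
    stop("force and velocity series must have equal length", call. = FALSE)
  }
  total_force * velocity
}

#' Names of the eight outcome variables
#'
#' @return Character vector of the eight variable names, in table order.
#' @export
pushup_variable_names <- function() {
  c("peak_hands_grf_BW", "peak_wholebody_grf_BW",
    "peak_wholebody_velocity_mps", "peak_wholebody_power_WperBW",
    "feet_grf_start_BW", "mean_feet_grf_BW",
    "wholebody_grf_at_peak_power_BW", "wholebody_velocity_at_peak_power_mps")
}

#' Extract the eight outcome variables
#'
#' Computes the eight body-weight-normalized outcome variables from the force,
#' velocity and power series of one calculation method: peak hands GRF, peak
#' whole-body GRF, peak whole-body velocity, peak whole-body power, feet GRF
#' at the starting position, mean feet GRF over the phase, and the whole-body
#' GRF and velocity read at the sample of peak power. Peaks are maxima of the
#' signed (upward-positive) series; on ties the first occurrence is used.
#' Forces are divided by body weight (dimensionless BW multiples); power is
#' divided by body weight in newtons (W per N of BW, numerically m/s).
#'
#' @param recording A [pushup_recording()] with filtered traces.
#' @param phase A `pushup_phase`.
#' @param baseline A `pushup_baseline`.
#' @param total_force,velocity,power The method's series over the phase.
#' @param method `"two_platform"` or `"one_platform"` (decides how the mean
#'   feet force is computed).
#' @return Named numeric vector of the eight variables.
#' @export
extract_variables <- function(recording, phase, baseline,
                              total_force, velocity, power,
                              method = c("two_platform", "one_platform")) {
  method <- match.arg(method)
  idx <- phase_indices(phase)
  if (length(idx) == 0) stop("empty phase", call. = FALSE)
  bw <- baseline$body_weight
  hands <- recording$hands$samples[idx]

  feet_mean <- if (method == "two_platform") {
    mean(recording$feet$samples[idx])
  } else {
    baseline$feet_static
  }
  i_pp <- which.max(power)  # first index on ties

  out <- c(
    peak_hands_grf_BW = max(hands) / bw,
    peak_wholebody_grf_BW = max(total_force) / bw,
    peak_wholebody_velocity_mps = max(velocity),
    peak_wholebody_power_WperBW = max(power) / bw,
    feet_grf_start_BW = baseline$feet_static / bw,
    mean_feet_grf_BW = feet_mean / bw,
    wholebody_grf_at_peak_power_BW = total_force[i_pp] / bw,
    wholebody_velocity_at_peak_power_mps = velocity[i_pp]
  )
  out
}
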