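#' Analyze one plyometric push-up trial
#'
#' The main fitting function of the package. Runs the full pipeline on a
#' recording — zero-phase low-pass filtering, static baseline estimation,
#' threshold-based phase detection on the hands trace, whole-body force
#' construction under the two-platform and/or one-platform method,
#' impulse-momentum velocity, power, and extraction of the eight outcome
#' variables. Both methods share the same detected phase and baseline.
#'
#' @param recording A [pushup_recording()]. When the feet trace is absent only
#'   the one-platform method is computed (and `body_mass` must be present).
#' @param config A [pushup_config()] or a named list of overrides.
#' @param methods Which calculation methods to run; defaults to all that are
#'   available for the recording.
#'
#' @return An object of class `pushup_kinetics` with components `methods`
#'   (per-method list of `time`, `total_force`, `velocity`, `power`,
#'   `variables`), `baseline`, `phase`, `config`, and the recording metadata.
#'   Supports [coef()], [summary()], [plot()] and [print()].
#' @examples
#' sim <- simulate_trial(sim_params(noise_sd_N = 0, seed = 1))
#' fit <- analyze_trial(sim$recording)
#' coef(fit)
#' @export
analyze_trial <- function(recording, config = pushup_config(),
                          methods = NULL) {
  config <- as_pushup_config(config)
  stopifnot(inherits(recording, "pushup_recording"))

  avail <- if (has_feet(recording)) c("two_platform", "one_platform")
           else "one_platform"
  if (is.null(methods)) methods <- avail
  methods <- match.arg(methods, c("two_platform", "one_platform"),
                       several.ok = TRUE)
  if (!all(methods %in% avail)) {
    stop("stage method-selection: two_platform requested but no feet trace",
         call. = FALSE)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  filt <- recording
  filt$hands <- stage("filter", lowpass_filter(recording$hands, config))
  if (has_feet(recording)) {
    filt$feet <- stage("filter", lowpass_filter(recording$feet, config))
  }
  baseline <- stage("baseline",
                    compute_baseline(filt, config, prefiltered = TRUE))
  phase <- stage("phase_detection",
                 detect_phase(filt$hands, baseline, config))

  fs <- filt$hands$sampling_rate
  tt <- (phase_indices(phase) - 1) / fs
  res <- list()
  for (m in methods) {
    total <- stage(m, if (m == "two_platform") {
      total_force_two_platform(filt, phase)
    } else {
      total_force_one_platform(filt, phase, baseline)
    })
    vel <- stage("velocity",
                 impulse_velocity(total, baseline$body_mass, config, fs))
    pow <- power_series(total, vel)
    vars <- extract_variables(filt, phase, baseline, total, vel, pow,
                              method = m)
    res[[m]] <- list(method = m, time = tt, total_force = total,
                     velocity = vel, power = pow, variables = vars)
  }

  structure(list(methods = res,
                 baseline = baseline,
                 phase = phase,
                 config = config,
                 sampling_rate = fs,
                 one_platform_only = !has_feet(recording),
                 participant_id = recording$participant_id,
                 trial_id = recording$trial_id,
                 sex = recording$sex),
            class = "pushup_kinetics")
}

#' @export
print.pushup_kinetics <- function(x, ...) {
  cat("Plyometric push-up kinetics\n")
  cat(sprintf("  trial:    %s / %s%s\n", x$participant_id, x$trial_id,
              if (x$one_platform_only) " (one-platform acquisition)" else ""))
  cat(sprintf("  body weight: %.1f N (%.1f kg); static split hands %.0f%% / feet %.0f%%\n",
              x$baseline$body_weight, x$baseline$body_mass,
              100 * x$baseline$hands_static / x$baseline$body_weight,
              100 * x$baseline$feet_static / x$baseline$body_weight))
  cat(sprintf("  phase:    %.3f-%.3f s (%d samples @ %g Hz)\n",
              x$phase$start_time_s, x$phase$end_time_s,
              phase_length(x$phase), x$sampling_rate))
  for (m in names(x$methods)) {
    v <- x$methods[[m]]$variables
    cat(sprintf("  %-13s peak v %.2f m/s, peak power %.2f W/BW, peak GRF %.2f BW\n",
                paste0(m, ":"), v[["peak_wholebody_velocity_mps"]],
                v[["peak_wholebody_power_WperBW"]],
                v[["peak_wholebody_grf_BW"]]))
  }
  invisible(x)
}

#' Eight outcome variables of a fitted trial
#'
#' @param object A `pushup_kinetics` object.
#' @param ... Unused.
#' @return Numeric matrix, one row per method, one column per variable.
#' @export
coef.pushup_kinetics <- function(object, ...) {
  do.call(rbind, lapply(object$methods, function(r) r$variables))
}

#' @export
summary.pushup_kinetics <- function(object, ...) {
  vars <- coef(object)
  out <- list(variables = vars,
              baseline = object$baseline,
              phase = object$phase,
              delta = if (nrow(vars) == 2) vars[2, ] - vars[1, ] else NULL)
  class(out) <- "summary.pushup_kinetics"
  out
}

#' @export
print.summary.pushup_kinetics <- function(x, ...) {
  cat("Outcome variables (rows = method):\n")
  print(round(x$variables, 4))
  if (!is.null(x$delta)) {
    cat("\nDifference (one_platform - two_platform):\n")
    print(round(x$delta, 4))
  }
  invisible(x)
}

#' Plot force, velocity and power time series of a fitted trial
#'
#' Three stacked panels (body-weight-normalized whole-body force, velocity,
#' power) over the detected push-up phase, one line per calculation method.
#'
#' @param x A `pushup_kinetics` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.pushup_kinetics <- function(x, ...) {
  bw <- x$baseline$body_weight
  tt <- x$methods[[1]]$time
  cols <- c(two_platform = "black", one_platform = "grey50")
  panels <- list(
    list(get = function(r) r$total_force / bw, ylab = "Force (BW)"),
    list(get = function(r) r$velocity, ylab = "Velocity (m/s)"),
    list(get = function(r) r$power / bw, ylab = "Power (W/BW)")
  )
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  for (p in panels) {
    ys <- sapply(x$methods, p$get)
    graphics::matplot(tt, ys, type = "l", lty = 1,
                      col = cols[names(x$methods)],
                      xlab = "Time (s)", ylab = p$ylab, ...)
    graphics::legend("topleft", legend = names(x$methods), lty = 1,
                     col = cols[names(x$methods)], bty = "n", cex = 0.8)
  }
  invisible(x)
}
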