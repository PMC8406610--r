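#' Analysis configuration
#'
#' Bundles the tunable constants of the push-up kinetics pipeline. Defaults
#' follow the standard acquisition setup for force-platform push-up testing:
#' 1000 Hz sampling, a 100 Hz low-pass Butterworth filter, and a 15 N force
#' threshold for movement onset and takeoff detection.
#'
#' @param gravity Gravitational acceleration in m/s^2.
#' @param filter_cutoff Low-pass filter cutoff in Hz (per-pass nominal cutoff;
#'   the filter is applied forward and backward for zero phase).
#' @param filter_order Butterworth filter order (per pass).
#' @param phase_threshold Force threshold in newtons used for both the onset
#'   rule (hands force dropping `phase_threshold` below its static value) and
#'   the takeoff rule (hands force dropping below `phase_threshold`).
#' @param baseline_window Duration in seconds of the initial quiescent window
#'   used to estimate static baselines.
#' @param sampling_rate_expected Nominal sampling rate in Hz. The actual rate
#'   is always inferred from the time column of a recording; this value is
#'   only used to warn on mismatch.
#' @param quiescence_sd Maximum force standard deviation (N) tolerated inside
#'   the baseline window before the baseline is declared unstable.
#'
#' @return An object of class `pushup_config`.
#' @examples
#' cfg <- pushup_config()
#' cfg$phase_threshold
#' @export
pushup_config <- function(gravity = 9.81,
                          filter_cutoff = 100,
                          filter_order = 4,
                          phase_threshold = 15,
                          baseline_window = 0.5,
                          sampling_rate_expected = 1000,
                          quiescence_sd = 10) {
  stopifnot(gravity > 0, filter_order >= 1, baseline_window > 0,
            sampling_rate_expected > 0, quiescence_sd > 0)
  if (phase_threshold <= 0) {
    stop("`phase_threshold` must be positive", call. = FALSE)
  }
  if (filter_cutoff <= 0 || filter_cutoff >= sampling_rate_expected / 2) {
    stop("`filter_cutoff` must lie in (0, sampling_rate_expected / 2)",
         call. = FALSE)
  }
  structure(
    list(gravity = gravity,
         filter_cutoff = filter_cutoff,
         filter_order = as.integer(filter_order),
         phase_threshold = phase_threshold,
         baseline_window = baseline_window,
         sampling_rate_expected = sampling_rate_expected,
         quiescence_sd = quiescence_sd),
    class = "pushup_config"
  )
}

#' @export
print.pushup_config <- function(x, ...) {
  cat("Push-up analysis configuration\n")
  cat(sprintf("  gravity:            %.3f m/s^2\n", x$gravity))
  cat(sprintf("  filter:             order-%d Butterworth, %.0f Hz, zero-phase\n",
              x$filter_order, x$filter_cutoff))
  cat(sprintf("  phase threshold:    %.1f N\n", x$phase_threshold))
  cat(sprintf("  baseline window:    %.2f s (quiescence SD < %.1f N)\n",
              x$baseline_window, x$quiescence_sd))
  cat(sprintf("  expected sampling:  %.0f Hz\n", x$sampling_rate_expected))
  invisible(x)
}

as_pushup_config <- function(config) {
  if (is.null(config)) return(pushup_config())
  if (inherits(config, "pushup_config")) return(config)
  if (is.list(config)) return(do.call(pushup_config, config))
  stop("`config` must be NULL, a pushup_config, or a named list", call. = FALSE)
}
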