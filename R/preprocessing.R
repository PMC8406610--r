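#' Zero-phase low-pass Butterworth filter
#'
#' Filters a force trace with a Butterworth low-pass filter applied forward
#' and backward (zero phase, unity DC gain). The trace is extended by
#' reflection at both ends before filtering to suppress startup transients in
#' the static baseline window; the nominal cutoff is used per pass, with no
#' double-pass cutoff correction.
#'
#' @param trace A [force_trace()].
#' @param config A [pushup_config()] supplying `filter_cutoff` and
#'   `filter_order`.
#'
#' @return A new [force_trace()] of identical length.
#' @export
lowpass_filter <- function(trace, config = pushup_config()) {
  config <- as_pushup_config(config)
  stopifnot(inherits(trace, "force_trace"))
  fs <- trace$sampling_rate
  nyq <- fs / 2
  if (config$filter_cutoff >= nyq) {
    stop("configuration error: filter cutoff (", config$filter_cutoff,
         " Hz) must be below the Nyquist frequency (", nyq, " Hz)",
         call. = FALSE)
  }
  x <- trace$samples
  n <- length(x)
  if (n <= 3 * config$filter_order) {
    stop("input error: trace too short for stable filtering", call. = FALSE)
  }
  bf <- signal::butter(config$filter_order, config$filter_cutoff / nyq,
                       type = "low")
  # pad long enough for the slowest pole's transient to decay below 1e-13
  r <- max(Mod(polyroot(rev(bf$a))))
  pad <- min(n - 1, max(3 * config$filter_order,
                        ceiling(log(1e-13) / log(min(r, 0.999)))))
  # reflect about the end points so the padded signal is continuous
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(left, x, right)
  # run each pass relative to its starting value so the zero initial state
  # of the recursion introduces no step transient
  one_pass <- function(z) {
    z0 <- z[1]
    as.numeric(signal::filter(bf, z - z0)) + z0
  }
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y <- y[(pad + 1):(pad + n)]
  force_trace(y, fs, trace$label)
}

#' Static baseline of a push-up recording
#'
#' Estimates body weight and the static hands/feet force split from the
#' initial quiescent hold. Hands and feet statics are the window means of the
#' filtered traces; body weight is their sum in two-platform mode, or
#' `body_mass * gravity` in one-platform mode (where the feet static is then
#' body weight minus the hands static, by construction).
#'
#' @param recording A [pushup_recording()].
#' @param config A [pushup_config()].
#' @param prefiltered Set `TRUE` when the recording's traces have already been
#'   low-pass filtered (as inside [analyze_trial()]), to avoid filtering
#'   twice.
#'
#' @return An object of class `pushup_baseline` with fields `body_weight`,
#'   `hands_static`, `feet_static` (all N), `body_mass` (kg) and `window`
#'   (start/end seconds actually used).
#' @export
compute_baseline <- function(recording, config = pushup_config(),
                             prefiltered = FALSE) {
  config <- as_pushup_config(config)
  stopifnot(inherits(recording, "pushup_recording"))
  fs <- recording$hands$sampling_rate
  n_win <- max(2L, min(length(recording$hands$samples),
                       as.integer(round(config$baseline_window * fs))))
  window <- c(0, n_win / fs)

  get_win <- function(trace) {
    tr <- if (prefiltered) trace else lowpass_filter(trace, config)
    tr$samples[seq_len(n_win)]
  }
  hands_win <- get_win(recording$hands)
  if (stats::sd(hands_win) >= config$quiescence_sd) {
    stop("unstable baseline: hands force SD over the baseline window is ",
         sprintf("%.1f", stats::sd(hands_win)), " N (limit ",
         config$quiescence_sd, " N)", call. = FALSE)
  }
  hands_static <- mean(hands_win)

  if (has_feet(recording)) {
    feet_win <- get_win(recording$feet)
    if (stats::sd(feet_win) >= config$quiescence_sd) {
      stop("unstable baseline: feet force SD over the baseline window is ",
           sprintf("%.1f", stats::sd(feet_win)), " N (limit ",
           config$quiescence_sd, " N)", call. = FALSE)
    }
    feet_static <- mean(feet_win)
    body_weight <- hands_static + feet_static
    body_mass <- body_weight / config$gravity
  } else {
    if (is.null(recording$body_mass)) {
      stop("missing mass: one-platform mode requires `body_mass` on the ",
           "recording", call. = FALSE)
    }
    body_mass <- recording$body_mass
    body_weight <- body_mass * config$gravity
    feet_static <- body_weight - hands_static
  }
  if (body_weight <= 0) stop("resolved body weight is not positive",
                             call. = FALSE)
  structure(list(body_weight = body_weight,
                 hands_static = hands_static,
                 feet_static = feet_static,
                 body_mass = body_mass,
                 window = window),
            class = "pushup_baseline")
}

#' @export
print.pushup_baseline <- function(x, ...) {
  cat(sprintf("<pushup_baseline: BW %.1f N (%.1f kg), hands %.1f N (%.0f%%), feet %.1f N (%.0f%%)>\n",
              x$body_weight, x$body_mass,
              x$hands_static, 100 * x$hands_static / x$body_weight,
              x$feet_static, 100 * x$feet_static / x$body_weight))
  invisible(x)
}
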