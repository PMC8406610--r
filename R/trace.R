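#' Vertical force trace from one platform
#'
#' A uniformly sampled vertical ground reaction force series from a single
#' force platform. Forces are in newtons with the upward reaction positive.
#'
#' @param samples Numeric vector of vertical force samples (N).
#' @param sampling_rate Sampling rate in Hz.
#' @param label Platform role, `"hands"` or `"feet"`.
#'
#' @return An object of class `force_trace`.
#' @examples
#' tr <- force_trace(c(450, 451, 449), 1000, "hands")
#' length(tr$samples)
#' @export
force_trace <- function(samples, sampling_rate, label = c("hands", "feet")) {
  label <- match.arg(label)
  samples <- as.numeric(samples)
  if (length(samples) < 2) {
    stop("a force trace needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("force samples must all be finite", call. = FALSE)
  }
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive number", call. = FALSE)
  }
  structure(list(samples = samples,
                 sampling_rate = sampling_rate,
                 label = label),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace: %s, %d samples @ %g Hz, range [%.1f, %.1f] N>\n",
              x$label, length(x$samples), x$sampling_rate,
              min(x$samples), max(x$samples)))
  invisible(x)
}

trace_time <- function(trace) {
  (seq_along(trace$samples) - 1) / trace$sampling_rate
}

#' Synchronized push-up recording
#'
#' Pairs the hands-platform trace with the (optional) feet-platform trace and
#' participant metadata. In one-platform acquisition mode `feet` is absent and
#' `body_mass` must be supplied so that body weight can be resolved.
#'
#' @param hands A [force_trace()] with label `"hands"`.
#' @param feet Optional [force_trace()] with label `"feet"`; must match the
#'   hands trace in length and sampling rate.
#' @param body_mass Participant body mass in kg. Optional in two-platform mode
#'   (it is then derived from the static baseline), required in one-platform
#'   mode.
#' @param participant_id,trial_id Identifiers carried through to outputs.
#' @param sex `"M"`, `"F"`, or `NA` when unknown.
#'
#' @return An object of class `pushup_recording`.
#' @export
pushup_recording <- function(hands, feet = NULL, body_mass = NULL,
                             participant_id = "P1", sex = NA_character_,
                             trial_id = "T1") {
  stopifnot(inherits(hands, "force_trace"))
  if (hands$label != "hands") stop("`hands` trace must have label 'hands'", call. = FALSE)
  if (!is.null(feet)) {
    stopifnot(inherits(feet, "force_trace"))
    if (feet$label != "feet") stop("`feet` trace must have label 'feet'", call. = FALSE)
    if (length(feet$samples) != length(hands$samples)) {
      stop("hands and feet traces must have equal length", call. = FALSE)
    }
    if (abs(feet$sampling_rate - hands$sampling_rate) >
        1e-9 * hands$sampling_rate) {
      stop("hands and feet traces must share the sampling rate", call. = FALSE)
    }
  }
  if (!is.null(body_mass)) {
    if (!is.finite(body_mass) || body_mass <= 0) {
      stop("`body_mass` must be positive", call. = FALSE)
    }
  }
  if (!is.na(sex) && !sex %in% c("M", "F")) {
    stop("`sex` must be 'M', 'F' or NA", call. = FALSE)
  }
  structure(list(hands = hands, feet = feet, body_mass = body_mass,
                 participant_id = as.character(participant_id),
                 sex = sex, trial_id = as.character(trial_id)),
            class = "pushup_recording")
}

#' @export
print.pushup_recording <- function(x, ...) {
  cat(sprintf("<pushup_recording: %s/%s, %s mode, %d samples @ %g Hz>\n",
              x$participant_id, x$trial_id,
              if (is.null(x$feet)) "one-platform" else "two-platform",
              length(x$hands$samples), x$hands$sampling_rate))
  invisible(x)
}

has_feet <- function(recording) !is.null(recording$feet)
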