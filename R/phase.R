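#' Detect the push-up phase on the hands trace
#'
#' Locates the push-up phase with the two first-crossing threshold rules:
#' the phase starts at the first sample where the (filtered) hands force is
#' strictly more than `phase_threshold` newtons below its static baseline,
#' and ends at the first subsequent sample where the hands force is strictly
#' below `phase_threshold` newtons (takeoff). Comparisons are strict, at
#' sample resolution, with no interpolation or debouncing.
#'
#' @param hands A filtered hands [force_trace()].
#' @param baseline A `pushup_baseline` from [compute_baseline()].
#' @param config A [pushup_config()].
#'
#' @return An object of class `pushup_phase` with `start_index` (inclusive),
#'   `end_index` (exclusive, i.e. one past the takeoff sample),
#'   `start_time_s`, `end_time_s`, and the baseline used. Indices are 1-based.
#' @export
detect_phase <- function(hands, baseline, config = pushup_config()) {
  config <- as_pushup_config(config)
  stopifnot(inherits(hands, "force_trace"),
            inherits(baseline, "pushup_baseline"))
  thr <- config$phase_threshold
  x <- hands$samples
  fs <- hands$sampling_rate

  start_idx <- which(x < baseline$hands_static - thr)[1]
  if (is.na(start_idx)) {
    stop("no movement: hands force never drops ", thr,
         " N below its static value", call. = FALSE)
  }
  end_candidates <- which(x < thr)
  end_idx <- end_candidates[end_candidates > start_idx][1]
  if (is.na(end_idx)) {
    if (length(end_candidates) > 0) {
      stop("ordering error: takeoff crossing found only before movement onset",
           call. = FALSE)
    }
    stop("no takeoff: hands force never drops below ", thr, " N",
         call. = FALSE)
  }
  duration <- (end_idx - start_idx) / fs
  if (duration <= 0.1) {
    stop("detected phase is implausibly short (", sprintf("%.3f", duration),
         " s <= 0.1 s)", call. = FALSE)
  }
  structure(list(start_index = start_idx,
                 end_index = end_idx + 1L,  # exclusive upper bound
                 start_time_s = (start_idx - 1) / fs,
                 end_time_s = (end_idx - 1) / fs,
                 baseline_used = baseline),
            class = "pushup_phase")
}

#' @export
print.pushup_phase <- function(x, ...) {
  cat(sprintf("<pushup_phase: samples [%d, %d), %.3f-%.3f s (%.3f s)>\n",
              x$start_index, x$end_index, x$start_time_s, x$end_time_s,
              x$end_time_s - x$start_time_s))
  invisible(x)
}

phase_indices <- function(phase) {
  if (phase$end_index <= phase$start_index) return(integer(0))
  seq(phase$start_index, phase$end_index - 1L)
}

phase_length <- function(phase) phase$end_index - phase$start_index
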