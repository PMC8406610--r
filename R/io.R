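#' Read a push-up recording from delimited text
#'
#' Reads a force-platform export with a header row, a time column and one
#' force column per platform, and returns a [pushup_recording()]. The sampling
#' rate is inferred from the median time step; the time column must be
#' strictly increasing and uniform within 1% relative step jitter. Comma and
#' tab delimiters are supported.
#'
#' @param path Path to a CSV/TSV file. Canonical columns are `time_s`,
#'   `fz_hands_N` and (optionally) `fz_feet_N`.
#' @param column_map Named list mapping roles to column names; entries `time`,
#'   `hands` and optionally `feet`.
#' @param config A [pushup_config()]; its `sampling_rate_expected` is used
#'   only to warn when the inferred rate disagrees by more than 1%.
#' @param body_mass,participant_id,sex,trial_id Metadata forwarded to
#'   [pushup_recording()].
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#'
#' @return A [pushup_recording()].
#' @export
read_recording <- function(path,
                           column_map = list(time = "time_s",
                                             hands = "fz_hands_N",
                                             feet = "fz_feet_N"),
                           config = pushup_config(),
                           body_mass = NULL, participant_id = "P1",
                           sex = NA_character_, trial_id = "T1",
                           delim = ",") {
  config <- as_pushup_config(config)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) < 2) stop("empty input: fewer than 2 data rows in ", path,
                         call. = FALSE)
  need <- c(time = column_map$time, hands = column_map$hands)
  missing_cols <- setdiff(unname(need), names(df))
  if (length(missing_cols) > 0) {
    stop("format error: missing mapped column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tt <- as.numeric(df[[column_map$time]])
  dt <- diff(tt)
  if (any(dt <= 0)) {
    stop("sampling error: time column is not strictly increasing",
         call. = FALSE)
  }
  dt_med <- stats::median(dt)
  if (any(abs(dt - dt_med) > 0.01 * dt_med)) {
    stop("sampling error: non-uniform time step (jitter beyond 1% of the ",
         "median step)", call. = FALSE)
  }
  rate <- 1 / dt_med
  if (abs(rate - config$sampling_rate_expected) >
      0.01 * config$sampling_rate_expected) {
    warning(sprintf("inferred sampling rate %.1f Hz differs from expected %.1f Hz",
                    rate, config$sampling_rate_expected), call. = FALSE)
  }
  hands <- force_trace(df[[column_map$hands]], rate, "hands")
  feet <- NULL
  if (!is.null(column_map$feet) && column_map$feet %in% names(df)) {
    feet <- force_trace(df[[column_map$feet]], rate, "feet")
  }
  pushup_recording(hands, feet, body_mass = body_mass,
                   participant_id = participant_id, sex = sex,
                   trial_id = trial_id)
}

#' Write analysis results as delimited text
#'
#' Emits a per-trial variables table (`variables.csv`, one row per method,
#' one column per outcome variable) and, optionally, one per-sample series
#' file per method (`series_<method>.csv` with columns `time_s`, `f_total_BW`,
#' `velocity_mps`, `power_WperBW`). Values are printed with 15 significant
#' digits so a read-back recovers them to better than 1e-9 relative.
#'
#' @param fit A `pushup_kinetics` object from [analyze_trial()].
#' @param path Output directory (created if needed).
#' @param series Write the per-sample series files too?
#'
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(fit, path, series = TRUE) {
  if (!inherits(fit, "pushup_kinetics")) {
    stop("`fit` must be a pushup_kinetics object", call. = FALSE)
  }
  if (length(fit$methods) == 0) stop("empty results: nothing to write",
                                     call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("I/O error: cannot create directory ", path,
                              call. = FALSE)
  written <- character(0)

  vars <- coef(fit)
  vt <- data.frame(participant_id = fit$participant_id,
                   trial_id = fit$trial_id,
                   sex = fit$sex,
                   method = rownames(vars),
                   stringsAsFactors = FALSE)
  vt <- cbind(vt, as.data.frame(vars))
  f_vars <- file.path(path, "variables.csv")
  write_numeric_csv(vt, f_vars)
  written <- c(written, f_vars)

  if (series) {
    bw <- fit$baseline$body_weight
    for (m in names(fit$methods)) {
      res <- fit$methods[[m]]
      sdf <- data.frame(time_s = res$time,
                        f_total_BW = res$total_force / bw,
                        velocity_mps = res$velocity,
                        power_WperBW = res$power / bw)
      f_ser <- file.path(path, paste0("series_", m, ".csv"))
      write_numeric_csv(sdf, f_ser)
      written <- c(written, f_ser)
    }
  }
  invisible(written)
}

# full-precision CSV writer: numeric columns at 15 significant digits
write_numeric_csv <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = 15, format = "g")
    }
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
}
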