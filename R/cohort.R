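#' Default population specification for cohort simulation
#'
#' Per-sex means and SDs of the participant-level simulator parameters, plus
#' the parameters shared by everyone. The defaults emulate a cohort of
#' physically active young adults (overall mass about 70 +/- 13 kg) in which
#' males load the hands more (smaller static feet share, deeper dip) and push
#' harder (larger propulsive acceleration) than females, reproducing the
#' direction of the sex contrasts in force-platform push-up testing.
#'
#' Each per-sex entry is `c(mean, sd)`; draws are from normal distributions
#' truncated to the parameter's validity range in `bounds`.
#'
#' @return A list with components `male`, `female`, `common`, `bounds`,
#'   `noise_sd_N` and `n_trials`, suitable for [simulate_cohort()] and
#'   round-trippable through YAML.
#' @export
cohort_spec <- function() {
  list(
    male = list(body_mass = c(77.1, 10.0),
                static_feet_share = c(0.33, 0.03),
                push_peak_accel = c(4.77, 0.45),
                feet_dip_depth = c(0.09, 0.015)),
    female = list(body_mass = c(63.3, 8.0),
                  static_feet_share = c(0.36, 0.04),
                  push_peak_accel = c(3.77, 0.45),
                  feet_dip_depth = c(0.06, 0.015)),
    common = list(quiet_duration_s = 1.0,
                  descent_duration_s = 0.40,
                  push_duration_s = 0.70,
                  descent_peak_accel = -3.0,
                  feet_end_share = 0.90,
                  tail_drop_g = 0.90,
                  tail_duration_s = 0.12),
    bounds = list(body_mass = c(40, 120),
                  static_feet_share = c(0.22, 0.50),
                  push_peak_accel = c(2.5, 7.0),
                  feet_dip_depth = c(0.02, 0.18)),
    noise_sd_N = 5,
    n_trials = 1
  )
}

# one truncated-normal draw; sd = 0 collapses to the mean
rtrunc_norm1 <- function(mean, sd, lo, hi) {
  if (sd <= 0) return(min(hi, max(lo, mean)))
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stop("truncated-normal rejection sampling failed (bounds too tight?)",
       call. = FALSE)
}

validate_spec <- function(spec) {
  for (nm in c("male", "female", "common", "bounds")) {
    if (is.null(spec[[nm]])) {
      stop("invalid population spec: missing component '", nm, "'",
           call. = FALSE)
    }
  }
  for (sex in c("male", "female")) {
    for (par in names(spec[[sex]])) {
      v <- spec[[sex]][[par]]
      if (length(v) != 2 || !all(is.finite(v)) || v[2] < 0) {
        stop("invalid population spec: ", sex, "$", par,
             " must be c(mean, sd) with sd >= 0", call. = FALSE)
      }
      if (is.null(spec$bounds[[par]])) {
        stop("invalid population spec: no bounds for '", par, "'",
             call. = FALSE)
      }
    }
  }
  invisible(spec)
}

#' Simulate a cohort of push-up trials
#'
#' Draws per-participant simulator parameters from sex-specific truncated
#' normal distributions and simulates `n_trials` recordings per participant.
#' Randomness is fully determined by `seed`: participant `i` draws parameters
#' under seed `seed + i * 1000` and trial `j` adds its sensor noise under seed
#' `seed + i * 1000 + j`, so streams are independent and reproducible.
#'
#' @param n_per_sex Participants per sex (17 gives the standard 34-subject
#'   cohort).
#' @param population A population spec as from [cohort_spec()].
#' @param n_trials Trials per participant (overrides the spec when given).
#' @param noise_sd_N Sensor noise SD in N (overrides the spec when given;
#'   set 0 for noiseless trials).
#' @param sampling_rate Sampling rate (Hz).
#' @param seed Integer root seed.
#' @param config A [pushup_config()].
#'
#' @return A list of class `pushup_cohort`; each element is a `pushup_sim`
#'   (recording + ground truth) whose recording carries participant id, sex
#'   and trial id.
#' @examples
#' coh <- simulate_cohort(n_per_sex = 2, seed = 1)
#' length(coh)
#' @export
simulate_cohort <- function(n_per_sex = 17, population = cohort_spec(),
                            n_trials = NULL, noise_sd_N = NULL,
                            sampling_rate = 1000, seed = 1,
                            config = pushup_config()) {
  stopifnot(n_per_sex >= 1)
  validate_spec(population)
  if (is.null(n_trials)) n_trials <- population$n_trials %||% 1
  if (is.null(noise_sd_N)) noise_sd_N <- population$noise_sd_N %||% 0

  out <- list()
  pid <- 0
  for (sex in c("M", "F")) {
    pop <- population[[if (sex == "M") "male" else "female"]]
    for (k in seq_len(n_per_sex)) {
      pid <- pid + 1
      set.seed(seed + pid * 1000)
      draw <- lapply(names(pop), function(par) {
        b <- population$bounds[[par]]
        rtrunc_norm1(pop[[par]][1], pop[[par]][2], b[1], b[2])
      })
      names(draw) <- names(pop)
      for (j in seq_len(n_trials)) {
        params <- do.call(sim_params, c(
          draw, population$common,
          list(noise_sd_N = noise_sd_N, seed = seed + pid * 1000 + j)))
        sim <- simulate_trial(params, sampling_rate, config)
        sim$recording$participant_id <- sprintf("P%02d", pid)
        sim$recording$sex <- sex
        sim$recording$trial_id <- sprintf("T%d", j)
        out[[length(out) + 1]] <- sim
      }
    }
  }
  structure(out, class = "pushup_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pushup_cohort <- function(x, ...) {
  sexes <- vapply(x, function(s) s$recording$sex, character(1))
  cat(sprintf("<pushup_cohort: %d trials (%d M, %d F)>\n",
              length(x), sum(sexes == "M"), sum(sexes == "F")))
  invisible(x)
}

#' Analyze every trial of a simulated or loaded cohort
#'
#' Runs [analyze_trial()] on each recording and stacks the eight outcome
#' variables into a long table, one row per trial x method. Trials failing
#' phase detection are skipped with a message rather than aborting the batch.
#'
#' @param recordings A `pushup_cohort`, or a plain list of
#'   [pushup_recording()] objects.
#' @param config A [pushup_config()].
#' @return A data.frame with columns `participant_id`, `sex`, `trial_id`,
#'   `method` and the eight variables. The skipped-trial reasons are attached
#'   as attribute `"skipped"`.
#' @export
analyze_cohort <- function(recordings, config = pushup_config()) {
  rows <- list()
  skipped <- character(0)
  for (item in recordings) {
    rec <- if (inherits(item, "pushup_sim")) item$recording else item
    fit <- tryCatch(analyze_trial(rec, config), error = function(e) e)
    if (inherits(fit, "error")) {
      skipped <- c(skipped, sprintf("%s/%s: %s", rec$participant_id,
                                    rec$trial_id, conditionMessage(fit)))
      next
    }
    vars <- coef(fit)
    for (m in rownames(vars)) {
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = rec$participant_id, sex = rec$sex,
        trial_id = rec$trial_id, method = m,
        as.data.frame(t(vars[m, ])), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no analyzable trials in the cohort",
                              call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
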