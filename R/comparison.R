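#' Build the method- or sex-comparison table for a cohort
#'
#' Reproduces the statistical layer of a force-platform method-comparison
#' study from a long trial-level variables table (as produced by
#' [analyze_cohort()]). Per participant and method, trials are first averaged
#' per variable; then, per variable:
#'
#' * `grouping = "method"`: paired t-test between the two-platform and
#'   one-platform values of the same participants, pooled-SD Cohen's d,
#'   Spearman correlation, and an OLS regression predicting the two-platform
#'   value from the one-platform value. The two variables that are identical
#'   across methods by construction (peak hands GRF and the feet GRF at the
#'   starting position) are emitted with blank comparison fields.
#' * `grouping = "sex"`: independent (pooled-variance) t-test between males
#'   and females on the two-platform values, with pooled-SD Cohen's d;
#'   correlation/regression fields are blank.
#'
#' Shapiro-Wilk normality p-values of the tested difference (or of each
#' group) are reported alongside but never gate the analysis.
#'
#' @param variables Data.frame with columns `participant_id`, `sex`,
#'   `trial_id`, `method` and the eight outcome variables.
#' @param grouping `"method"` or `"sex"`.
#' @param cor_method Correlation type for the method comparison.
#' @return An object of class `pushup_comparison`: a data.frame with one row
#'   per variable (means, SDs, mean difference, 95% CI, p, Cohen's d and
#'   band, r and band, slope/intercept/r-squared), with the grouping stored
#'   as an attribute. Supports [print()] and [predict()].
#' @export
build_comparison <- function(variables, grouping = c("method", "sex"),
                             cor_method = "spearman") {
  grouping <- match.arg(grouping)
  needed <- c("participant_id", "sex", "trial_id", "method",
              pushup_variable_names())
  missing_cols <- setdiff(needed, names(variables))
  if (length(missing_cols) > 0) {
    stop("variables table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  # per-participant trial means, per method
  agg <- stats::aggregate(
    variables[pushup_variable_names()],
    by = list(participant_id = variables$participant_id,
              sex = variables$sex, method = variables$method),
    FUN = mean)

  blank_vars <- c("peak_hands_grf_BW", "feet_grf_start_BW")
  rows <- list()

  if (grouping == "method") {
    two <- agg[agg$method == "two_platform", ]
    one <- agg[agg$method == "one_platform", ]
    if (nrow(two) == 0 || nrow(one) == 0) {
      stop("method comparison needs both methods in the table", call. = FALSE)
    }
    if (nrow(two) != nrow(one)) {
      stop("unbalanced pairing: unequal participant counts per method",
           call. = FALSE)
    }
    two <- two[order(two$participant_id), ]
    one <- one[order(one$participant_id), ]
    if (!all(two$participant_id == one$participant_id)) {
      stop("unbalanced pairing: participants differ between methods",
           call. = FALSE)
    }
    if (nrow(two) < 3) stop("need at least 3 participants per cell",
                            call. = FALSE)
    for (v in pushup_variable_names()) {
      x <- two[[v]]; y <- one[[v]]
      row <- data.frame(variable = v,
                        mean_a = mean(x), sd_a = stats::sd(x),
                        mean_b = mean(y), sd_b = stats::sd(y),
                        stringsAsFactors = FALSE)
      if (v %in% blank_vars) {
        row[c("mean_diff", "ci_low", "ci_high", "p", "d")] <- NA_real_
        row$d_band <- NA_character_
        row[c("r", "r_p")] <- NA_real_
        row$r_band <- NA_character_
        row[c("slope", "intercept", "r_squared", "shapiro_p")] <- NA_real_
      } else {
        pt <- paired_t(x, y)
        dd <- cohens_d(mean(x), stats::sd(x), mean(y), stats::sd(y))
        cr <- correlate(y, x, method = cor_method)
        rg <- simple_regression(y, x)  # predict two-platform from one
        sw <- tryCatch(stats::shapiro.test(x - y)$p.value,
                       error = function(e) NA_real_)
        row$mean_diff <- pt$mean_diff
        row$ci_low <- pt$ci[1]; row$ci_high <- pt$ci[2]
        row$p <- pt$p; row$d <- dd$d; row$d_band <- dd$band
        row$r <- cr$r; row$r_p <- cr$p; row$r_band <- cr$band
        row$slope <- rg$slope; row$intercept <- rg$intercept
        row$r_squared <- rg$r_squared
        row$shapiro_p <- sw
      }
      rows[[v]] <- row
    }
    labels <- c(a = "two_platform", b = "one_platform")
  } else {
    base <- agg[agg$method == "two_platform", ]
    if (nrow(base) == 0) base <- agg  # single-method tables
    males <- base[base$sex == "M", ]
    females <- base[base$sex == "F", ]
    if (nrow(males) < 3 || nrow(females) < 3) {
      stop("need at least 3 participants per sex", call. = FALSE)
    }
    for (v in pushup_variable_names()) {
      x <- males[[v]]; y <- females[[v]]
      it <- independent_t(x, y)
      dd <- cohens_d(mean(x), stats::sd(x), mean(y), stats::sd(y))
      swx <- tryCatch(stats::shapiro.test(x)$p.value,
                      error = function(e) NA_real_)
      rows[[v]] <- data.frame(
        variable = v,
        mean_a = mean(x), sd_a = stats::sd(x),
        mean_b = mean(y), sd_b = stats::sd(y),
        mean_diff = it$mean_diff, ci_low = it$ci[1], ci_high = it$ci[2],
        p = it$p, d = dd$d, d_band = dd$band,
        r = NA_real_, r_p = NA_real_, r_band = NA_character_,
        slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
        shapiro_p = swx,
        stringsAsFactors = FALSE)
    }
    labels <- c(a = "male", b = "female")
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "grouping") <- grouping
  attr(out, "group_labels") <- labels
  class(out) <- c("pushup_comparison", "data.frame")
  out
}

#' @export
print.pushup_comparison <- function(x, digits = 4, ...) {
  labels <- attr(x, "group_labels")
  cat(sprintf("Push-up method-comparison table (grouping: %s; a = %s, b = %s)\n\n",
              attr(x, "grouping"), labels[["a"]], labels[["b"]]))
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    cat(sprintf("  %-38s %5.2f +/- %4.2f vs %5.2f +/- %4.2f",
                r$variable, r$mean_a, r$sd_a, r$mean_b, r$sd_b))
    if (is.na(r$d)) {
      cat("   --\n")
    } else {
      cat(sprintf("   d = %.2f (%s), p = %.4f\n", r$d, r$d_band, r$p))
    }
  }
  invisible(x)
}

#' Predict two-platform values from one-platform values
#'
#' Applies the stored per-variable regression coefficients of a method
#' comparison (`two_platform ~ one_platform`) to new one-platform
#' measurements.
#'
#' @param object A `pushup_comparison` built with `grouping = "method"`.
#' @param newdata Numeric vector of one-platform values.
#' @param variable Name of the outcome variable the values belong to.
#' @param ... Unused.
#' @return Predicted two-platform values.
#' @export
predict.pushup_comparison <- function(object, newdata, variable, ...) {
  if (attr(object, "grouping") != "method") {
    stop("predictions require a method-grouped comparison", call. = FALSE)
  }
  i <- match(variable, object$variable)
  if (is.na(i)) stop("unknown variable: ", variable, call. = FALSE)
  if (is.na(object$slope[i])) {
    stop("no regression available for ", variable, call. = FALSE)
  }
  object$slope[i] * newdata + object$intercept[i]
}

#' Write a comparison table as CSV
#'
#' @param comparison A `pushup_comparison`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_comparison <- function(comparison, path) {
  df <- as.data.frame(comparison)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(z) round(z, 6))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
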