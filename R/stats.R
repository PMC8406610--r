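#' Interpretation band for a Cohen's d effect size
#'
#' Bands: `< 0.20` trivial, `< 0.50` small, `< 0.80` moderate, otherwise
#' large.
#'
#' @param d Effect-size magnitude(s).
#' @return Character vector of band labels.
#' @export
d_band <- function(d) {
  d <- abs(d)
  cut(d, breaks = c(-Inf, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("trivial", "small", "moderate", "large")) |> as.character()
}

#' Strength band for a correlation coefficient
#'
#' Bands on `|r|`: `<= 0.30` minor, `<= 0.50` moderate, `<= 0.70` large,
#' `<= 0.90` very large, `<= 1` perfect (values at or below 0.10 are labeled
#' negligible).
#'
#' @param r Correlation coefficient(s).
#' @return Character vector of band labels.
#' @export
r_band <- function(r) {
  a <- abs(r)
  cut(a, breaks = c(-Inf, 0.10, 0.30, 0.50, 0.70, 0.90, Inf), right = TRUE,
      labels = c("negligible", "minor", "moderate", "large", "very large",
                 "perfect")) |> as.character()
}

#' Cohen's d from group summaries (pooled-SD form)
#'
#' `d = |mean_a - mean_b| / sqrt((sd_a^2 + sd_b^2) / 2)`, the root-mean-square
#' pooled SD of the two groups, with an interpretation band attached. This
#' form is used for both paired (method) and independent (sex) comparisons;
#' see [cohens_d_paired()] for the difference-score variant.
#'
#' @param mean_a,sd_a,mean_b,sd_b Group means and SDs.
#' @return A list with `d` and `band`.
#' @examples
#' cohens_d(0.90, 0.23, 1.39, 0.37)$d  # 1.59
#' @export
cohens_d <- function(mean_a, sd_a, mean_b, sd_b) {
  if (sd_a < 0 || sd_b < 0) stop("SDs must be non-negative", call. = FALSE)
  if (sd_a == 0 && sd_b == 0) {
    stop("undefined effect size: both SDs are zero", call. = FALSE)
  }
  d <- abs(mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2)
  list(d = d, band = d_band(d))
}

#' Cohen's d, difference-score variant for paired data
#'
#' `d = |mean(x - y)| / sd(x - y)`. Provided as an alternative to the pooled
#' form for paired comparisons.
#'
#' @param x,y Paired sample vectors.
#' @return A list with `d` and `band`.
#' @export
cohens_d_paired <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  dif <- x - y
  s <- stats::sd(dif)
  if (s == 0) stop("undefined effect size: zero-variance differences",
                   call. = FALSE)
  d <- abs(mean(dif)) / s
  list(d = d, band = d_band(d))
}

#' Paired t-test with mean difference and 95% CI
#'
#' Standard paired t on the differences `x - y`. When the differences have
#' exactly zero variance the test statistic is undefined; the result is then
#' flagged degenerate with `p = NA`.
#'
#' @param x,y Paired sample vectors of equal length (n >= 3), no missing
#'   pairs.
#' @return List with `t`, `df`, `p`, `mean_diff`, `ci` (95%), `degenerate`.
#' @export
paired_t <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("paired samples must have equal length",
                           call. = FALSE)
  if (n < 3) stop("paired t-test needs n >= 3", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing pairs are not allowed",
                                 call. = FALSE)
  dif <- x - y
  if (stats::sd(dif) == 0) {
    return(list(t = NA_real_, df = n - 1, p = NA_real_,
                mean_diff = mean(dif), ci = c(mean(dif), mean(dif)),
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE, conf.level = 0.95)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate),
       ci = as.numeric(tt$conf.int), degenerate = FALSE)
}

#' Independent two-sample t-test (pooled variance)
#'
#' Equal-variance two-sample t with `df = n_a + n_b - 2`, mean difference and
#' 95% CI.
#'
#' @param group_a,group_b Sample vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`, `mean_diff`, `ci`.
#' @export
independent_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE, conf.level = 0.95)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(diff(rev(tt$estimate))),
       ci = as.numeric(tt$conf.int))
}

#' Correlation with strength band
#'
#' Spearman (default) or Pearson correlation with the coefficient's strength
#' band attached.
#'
#' @param x,y Sample vectors (n >= 3).
#' @param method `"spearman"` or `"pearson"`.
#' @return List with `r`, `p`, `band`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) < 3 || length(y) != length(x)) {
    stop("correlation needs n >= 3 paired values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input vector", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value,
       band = r_band(unname(ct$estimate)))
}

#' Simple linear regression
#'
#' Ordinary least squares fit of `y` on `x`; returns slope, intercept and
#' r-squared.
#'
#' @param x,y Sample vectors (n >= 3), `x` not constant.
#' @return List with `slope`, `intercept`, `r_squared`, and the underlying
#'   `lm` fit.
#' @export
simple_regression <- function(x, y) {
  if (length(x) < 3 || length(y) != length(x)) {
    stop("regression needs n >= 3 paired values", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("regression undefined for constant x",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  # suppressed: summary() warns on exactly collinear input, a legal case here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       fit = fit)
}
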