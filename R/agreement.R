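#' Regression agreement between two pipelines
#'
#' OLS of `y` on `x` with R-squared and the slope bias
#' `(slope - 1) * 100` in percent: the summary used to compare Centiloid
#' values from two processing pipelines.
#'
#' @param x,y paired value vectors (n >= 3, `var(x) > 0`).
#' @return An `agreement_report`: `slope`, `intercept`, `r2`,
#'   `slope_bias_pct`, `n`.
#' @export
regression_agreement <- function(x, y) {
  if (length(x) != length(y)) stop("regression_agreement: unpaired inputs")
  if (length(x) < 3) stop("regression_agreement: need n >= 3")
  if (stats::var(x) <= 0)
    stop("regression_agreement: degenerate x variance")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = suppressWarnings(summary(fit)$r.squared),
                 slope_bias_pct = (slope - 1) * 100,
                 n = length(x)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("<agreement_report> slope %.3f (bias %+.1f%%), ",
                     "intercept %.3f, R2 %.3f, n = %d\n"),
              x$slope, x$slope_bias_pct, x$intercept, x$r2, x$n))
  invisible(x)
}

#' ICC(A,1): two-way, absolute agreement, single measurement
#'
#' Intraclass correlation from the two-way ANOVA decomposition
#' (McGraw-Wong ICC(A,1)):
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`,
#' where MSR, MSC, MSE are the subject, rater, and residual mean squares.
#' Absolute agreement penalizes systematic offsets between raters, unlike
#' the consistency form.
#'
#' @param ratings n x k numeric matrix (or data frame) of paired
#'   measurements; here k = 2 pipelines. No missing cells.
#' @return The ICC value (scalar, <= 1).
#' @export
icc_absolute_single <- function(ratings) {
  m <- as.matrix(ratings)
  if (any(!is.finite(m))) stop("icc_absolute_single: missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2)
    stop("icc_absolute_single: need n >= 3 subjects and k >= 2 raters")
  if (stats::var(as.vector(m)) <= 0)
    stop("icc_absolute_single: constant ratings, variance degenerate")
  grand <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  resid <- m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Consistency ICC, single measurement (ICC(C,1))
#'
#' Companion to [icc_absolute_single] that ignores systematic rater
#' offsets: `(MSR - MSE) / (MSR + (k-1) MSE)`.
#' @inheritParams icc_absolute_single
#' @export
icc_consistency_single <- function(ratings) {
  m <- as.matrix(ratings)
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) stop("icc_consistency_single: need n >= 3, k >= 2")
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  resid <- m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

#' Relative variance as an SD ratio
#'
#' Ratio of the Centiloid standard deviation of a method to that of the
#' baseline (standard-pipeline PiB) in the same young-control group. Every
#' published table value is reproduced by the SD ratio (not the ratio of
#' variances); the conventional name is kept.
#'
#' @param sd_numerator,sd_baseline standard deviations; baseline > 0.
#' @return The full-precision ratio, with a `rounded` attribute at 2 dp
#'   (half-up).
#' @export
relative_variance <- function(sd_numerator, sd_baseline) {
  if (any(sd_baseline <= 0))
    stop("relative_variance: baseline SD must be positive")
  if (any(sd_numerator < 0))
    stop("relative_variance: SD must be nonnegative")
  rv <- sd_numerator / sd_baseline
  attr(rv, "rounded") <- round_half_up(rv, 2)
  rv
}

# round half away from zero at `digits` decimals (spreadsheet convention,
# used for table reproduction; R's round() is banker's rounding)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Full agreement report between two pipelines
#'
#' Combines OLS agreement and ICC(A,1) for a paired table, the comparison
#' applied to validation cohorts measured by both the standard and the
#' MRI-less pipeline.
#'
#' @param value_standard,value_nonstandard paired vectors.
#' @return list: `r2`, `slope`, `intercept`, `slope_bias_pct`, `icc`, `n`.
#' @export
pipeline_agreement <- function(value_standard, value_nonstandard) {
  reg <- regression_agreement(value_standard, value_nonstandard)
  icc <- icc_absolute_single(cbind(value_standard, value_nonstandard))
  list(r2 = reg$r2, slope = reg$slope, intercept = reg$intercept,
       slope_bias_pct = reg$slope_bias_pct, icc = icc, n = reg$n)
}

#' Bundled young-control Centiloid variability table
#'
#' Published group means and SDs of Centiloid values in the young controls
#' of each calibration dataset, for both pipelines and (where applicable)
#' both tracers. Input data for relative-variance summaries.
#'
#' @return data frame with columns `dataset`, `n`, `measure`
#'   (`pib_std`, `pib_ns`, `tracer_std`, `tracer_ns`), `mean`, `sd`,
#'   `published_rv` (the table's own 2-dp relative variance, NA for the
#'   baseline).
#' @export
yc_variability_table <- function() {
  path <- system.file("extdata", "yc_centiloid_variability.csv",
                      package = "centiloidr", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Relative variances recomputed from the bundled table
#'
#' For every non-baseline row, the SD ratio against the standard-pipeline
#' PiB SD of the same dataset, at full precision and rounded to 2 dp.
#' @return data frame: `dataset`, `measure`, `rv`, `rv_2dp`,
#'   `published_rv`.
#' @export
yc_relative_variances <- function() {
  tab <- yc_variability_table()
  base <- tab[tab$measure == "pib_std", c("dataset", "sd")]
  names(base)[2] <- "sd_base"
  x <- merge(tab[tab$measure != "pib_std", ], base, by = "dataset")
  rv <- as.numeric(relative_variance(x$sd, x$sd_base))
  out <- data.frame(dataset = x$dataset, measure = x$measure, rv = rv,
                    rv_2dp = round_half_up(rv, 2),
                    published_rv = x$published_rv)
  out[order(out$dataset, out$measure), ]
}
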