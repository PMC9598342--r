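# Agreement statistics for RR predictions: MAE, RMSE, coefficient of
# determination, Pearson r, 2SD and Bland-Altman limits of agreement.
# Error convention throughout: error = predicted - truth (bpm).

#' Prediction set
#'
#' Pairs predicted RR values with their ground truth. All dispersion
#' statistics require at least two pairs.
#'
#' @param rr_pred numeric vector of predicted RR (bpm).
#' @param rr_true numeric vector of reference RR (bpm), same length.
#' @return object of class `prediction_set` with elements `rr_pred`,
#'   `rr_true`, `n`.
#' @export
prediction_set <- function(rr_pred, rr_true) {
  rr_pred <- as.numeric(rr_pred)
  rr_true <- as.numeric(rr_true)
  if (length(rr_pred) != length(rr_true))
    stop("rr_pred and rr_true must have equal length")
  if (length(rr_pred) == 0L) stop("empty prediction set")
  if (!all(is.finite(rr_pred)) || !all(is.finite(rr_true)))
    stop("non-finite values in prediction set")
  structure(list(rr_pred = rr_pred, rr_true = rr_true, n = length(rr_pred)),
            class = "prediction_set")
}

as_prediction_set <- function(ps) {
  if (inherits(ps, "prediction_set")) return(ps)
  if (is.list(ps) && !is.null(ps$rr_pred)) return(prediction_set(ps$rr_pred, ps$rr_true))
  stop("expected a prediction_set")
}

#' Mean absolute error
#' @param ps a [prediction_set()].
#' @return MAE in bpm.
#' @export
rr_mae <- function(ps) {
  ps <- as_prediction_set(ps)
  mean(abs(ps$rr_pred - ps$rr_true))
}

#' Root mean squared error
#' @param ps a [prediction_set()].
#' @return RMSE in bpm; always >= [rr_mae()].
#' @export
rr_rmse <- function(ps) {
  ps <- as_prediction_set(ps)
  sqrt(mean((ps$rr_pred - ps$rr_true)^2))
}

#' Coefficient of determination (MSE-ratio form)
#'
#' `1 - MSE_model / MSE_baseline`, where the baseline predicts the mean of the
#' ground truth. This is the usual R-squared; it is reported alongside the
#' Pearson correlation because agreement tables in this field use "R" for both.
#'
#' @param ps a [prediction_set()].
#' @return dimensionless value, at most 1.
#' @export
rr_r2 <- function(ps) {
  ps <- as_prediction_set(ps)
  if (ps$n < 2L) stop("need n >= 2")
  mse_base <- mean((ps$rr_true - mean(ps$rr_true))^2)
  if (mse_base == 0) stop("constant ground truth: baseline MSE is zero")
  1 - mean((ps$rr_pred - ps$rr_true)^2) / mse_base
}

#' Pearson correlation between prediction and truth
#' @param ps a [prediction_set()].
#' @return correlation in [-1, 1].
#' @export
rr_pearson <- function(ps) {
  ps <- as_prediction_set(ps)
  if (ps$n < 2L) stop("need n >= 2")
  if (sd(ps$rr_pred) == 0 || sd(ps$rr_true) == 0)
    stop("zero variance: correlation undefined")
  cor(ps$rr_pred, ps$rr_true)
}

# population (divisor n) standard deviation of the signed error
error_sd_pop <- function(ps) {
  e <- ps$rr_pred - ps$rr_true
  sqrt(mean((e - mean(e))^2))
}

#' 2SD spread statistic
#'
#' 1.96 times the population standard deviation (divisor n) of the signed
#' error; the half-width of the 95 % limits of agreement.
#'
#' @param ps a [prediction_set()].
#' @return bpm.
#' @export
rr_two_sd <- function(ps) {
  ps <- as_prediction_set(ps)
  if (ps$n < 2L) stop("need n >= 2")
  1.96 * error_sd_pop(ps)
}

#' 95 % limits of agreement
#'
#' `mean(error) +/- 1.96 * SD(error)` with the population SD, so that
#' `(upper - lower) / 2` equals [rr_two_sd()] exactly.
#'
#' @param ps a [prediction_set()].
#' @return named numeric vector `c(lower, upper)` in bpm.
#' @export
rr_loa <- function(ps) {
  ps <- as_prediction_set(ps)
  if (ps$n < 2L) stop("need n >= 2")
  m <- mean(ps$rr_pred - ps$rr_true)
  h <- 1.96 * error_sd_pop(ps)
  c(lower = m - h, upper = m + h)
}

#' Bland-Altman plot data
#'
#' Per-pair means and differences plus the bias and limits-of-agreement lines.
#'
#' @param ps a [prediction_set()].
#' @return list with `data` (data.frame `mean`, `diff`), `bias`, `loa_lower`,
#'   `loa_upper`.
#' @export
bland_altman_data <- function(ps) {
  ps <- as_prediction_set(ps)
  if (ps$n < 2L) stop("need n >= 2")
  d <- ps$rr_pred - ps$rr_true
  loa <- rr_loa(ps)
  list(data = data.frame(mean = (ps$rr_pred + ps$rr_true) / 2, diff = d),
       bias = mean(d),
       loa_lower = unname(loa["lower"]),
       loa_upper = unname(loa["upper"]))
}

#' Regression-plot trendline
#'
#' Least-squares trendline of prediction on truth; the ideal trendline is
#' `y = x`.
#'
#' @param ps a [prediction_set()].
#' @return list with `slope`, `intercept`.
#' @export
regression_data <- function(ps) {
  ps <- as_prediction_set(ps)
  if (ps$n < 2L) stop("need n >= 2")
  fit <- lm(ps$rr_pred ~ ps$rr_true)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}

#' Paired two-sided t-test on per-window errors
#'
#' Compares two models through their per-window absolute errors. Uses the
#' textbook statistic `t = mean(d) / (sd(d)/sqrt(n))` with the sample SD
#' (divisor n-1). Identical inputs return `t = 0, p = 1` rather than erroring
#' on a constant difference.
#'
#' @param abs_err_a,abs_err_b equal-length numeric vectors of absolute errors.
#' @return list with `t`, `p`, `df`.
#' @export
paired_ttest <- function(abs_err_a, abs_err_b) {
  if (length(abs_err_a) != length(abs_err_b)) stop("mismatched lengths")
  n <- length(abs_err_a)
  if (n < 2L) stop("need n >= 2")
  d <- as.numeric(abs_err_a) - as.numeric(abs_err_b)
  s <- sd(d)
  if (s == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    t_stat <- mean(d) / (s / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
  }
  list(t = t_stat, p = p, df = n - 1L)
}

#' Full metrics report for a prediction set
#'
#' Computes all agreement statistics and asserts their internal identities
#' (`rmse >= mae`, LOA half-width equals 2SD, `r2 <= 1`, `|pearson| <= 1`).
#'
#' @param ps a [prediction_set()].
#' @param scenario optional character tag carried into the report.
#' @return object of class `metrics_report`: list with `mae`, `rmse`, `r2`,
#'   `pearson_r`, `two_sd`, `loa_lower`, `loa_upper`, `mean_error`, `n`,
#'   `scenario`.
#' @export
metrics_report <- function(ps, scenario = NA_character_) {
  ps <- as_prediction_set(ps)
  if (ps$n < 2L) stop("need n >= 2 for a metrics report")
  loa <- rr_loa(ps)
  rep <- structure(list(
    mae = rr_mae(ps),
    rmse = rr_rmse(ps),
    r2 = rr_r2(ps),
    pearson_r = rr_pearson(ps),
    two_sd = rr_two_sd(ps),
    loa_lower = unname(loa["lower"]),
    loa_upper = unname(loa["upper"]),
    mean_error = mean(ps$rr_pred - ps$rr_true),
    n = ps$n,
    scenario = scenario
  ), class = "metrics_report")
  stopifnot(rep$rmse >= rep$mae - 1e-12,
            abs((rep$loa_upper - rep$loa_lower) / 2 - rep$two_sd) < 1e-9,
            rep$r2 <= 1 + 1e-12,
            abs(rep$pearson_r) <= 1 + 1e-12)
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("RR metrics (n = %d%s)\n", x$n,
              if (is.na(x$scenario)) "" else paste0(", ", x$scenario)))
  cat(sprintf("  MAE  %.4f bpm   RMSE %.4f bpm\n", x$mae, x$rmse))
  cat(sprintf("  R2   %.4f       Pearson r %.4f\n", x$r2, x$pearson_r))
  cat(sprintf("  bias %.4f bpm   LOA [%.4f, %.4f]   2SD %.4f\n",
              x$mean_error, x$loa_lower, x$loa_upper, x$two_sd))
  invisible(x)
}
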