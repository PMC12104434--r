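# Model development: closed-form ordinary least squares for SA ~ PAH with
# the residual diagnostics used when the published equations were derived
# (Durbin-Watson autocorrelation, Kolmogorov-Smirnov residual normality,
# residual-on-fitted homoscedasticity regression).

#' Fit a simple linear model by closed-form OLS
#'
#' `slope = cov(x, y) / var(x)`, `intercept = mean(y) - slope * mean(x)`;
#' residual standard deviation uses the n - 2 denominator; coefficient
#' standard errors are the classical OLS expressions.
#'
#' @param x Predictor values (PAH, percent).
#' @param y Response values (skeletal age, years).
#' @return A `linear_model_spec` carrying `fitted` and `residuals` as
#'   attributes.
#' @export
fit_linear_model <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("at least 3 observations are required")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values in input")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop("degenerate design: predictor is constant")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  res <- y - fitted
  rss <- sum(res^2)
  sigma <- sqrt(rss / (n - 2))
  se_slope <- sigma / sqrt(sxx)
  se_intercept <- sigma * sqrt(1 / n + mean(x)^2 / sxx)
  syy <- sum((y - mean(y))^2)
  r2 <- if (syy > 0) 1 - rss / syy else NA_real_
  r <- if (!is.na(r2)) sign(slope) * sqrt(max(r2, 0)) else NA_real_
  spec <- linear_model_spec(intercept, slope, residual_sd = sigma, r = r,
                            r_squared = if (is.na(r2)) NA_real_ else min(max(r2, 0), 1),
                            se_intercept = se_intercept, se_slope = se_slope,
                            n = as.integer(n))
  attr(spec, "fitted") <- fitted
  attr(spec, "residuals") <- res
  spec
}

#' Durbin-Watson statistic
#'
#' `sum((e_t - e_(t-1))^2) / sum(e_t^2)` over the residuals in the given
#' order. Values near 2 indicate no first-order autocorrelation.
#'
#' @param residuals Ordered residuals (length >= 2, not all zero).
#' @return The statistic, in \[0, 4\].
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) stop("at least 2 residuals are required")
  denom <- sum(residuals^2)
  if (denom == 0) stop("Durbin-Watson undefined: all residuals are zero")
  sum(diff(residuals)^2) / denom
}

#' Residual diagnostics for a fitted SA ~ PAH model
#'
#' Three checks: (1) homoscedasticity, by regressing the residuals on the
#' fitted values (for exact OLS residuals slope and R^2 are zero up to
#' numerical noise); (2) residual normality, by a Kolmogorov-Smirnov
#' statistic against a normal with mean 0 and the residuals' sample
#' standard deviation, with a parametric-bootstrap p-value
#' (Lilliefors-style calibration, since estimating the scale invalidates
#' the classical KS null); (3) the Durbin-Watson statistic.
#'
#' @param fitted Fitted (predicted) values.
#' @param residuals Residuals, same length.
#' @param B Bootstrap replicates for the KS p-value (default 1999).
#' @param seed Optional integer seed for the bootstrap.
#' @param dw_order `"input"` (default) keeps the given row order for
#'   Durbin-Watson; `"fitted"` sorts by fitted value first (cross-sectional
#'   data has no natural time order).
#' @return A `fit_diagnostics` list: `durbin_watson`, `ks_statistic`,
#'   `ks_pvalue`, `homoscedasticity_slope`, `homoscedasticity_r2`.
#' @export
residual_diagnostics <- function(fitted, residuals, B = 1999, seed = NULL,
                                 dw_order = c("input", "fitted")) {
  dw_order <- match.arg(dw_order)
  if (length(fitted) != length(residuals)) {
    stop("fitted and residuals must have equal length")
  }
  n <- length(residuals)
  if (n < 3) stop("at least 3 observations are required")

  hom <- fit_linear_model(fitted, residuals)
  e <- if (dw_order == "fitted") residuals[order(fitted)] else residuals
  dw <- durbin_watson(e)

  sdhat <- stats::sd(residuals)
  if (sdhat == 0) stop("residuals are constant; KS normality test undefined")
  ks_stat_of <- function(v) {
    s <- stats::sd(v)
    as.numeric(suppressWarnings(stats::ks.test(v, "pnorm", 0, s))$statistic)
  }
  obs <- ks_stat_of(residuals)
  if (!is.null(seed)) set.seed(seed)
  boot <- replicate(B, ks_stat_of(stats::rnorm(n, 0, sdhat)))
  pval <- (1 + sum(boot >= obs)) / (B + 1)

  structure(list(
    durbin_watson = dw,
    ks_statistic = obs,
    ks_pvalue = pval,
    homoscedasticity_slope = hom$slope,
    homoscedasticity_r2 = hom$r_squared
  ), class = "fit_diagnostics")
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf("Durbin-Watson %.3f | KS D %.4f (p %.3f) | residual~fitted slope %.2e, R^2 %.2e\n",
              x$durbin_watson, x$ks_statistic, x$ks_pvalue,
              x$homoscedasticity_slope, x$homoscedasticity_r2))
  invisible(x)
}

#' Fit general and stage-specific SA ~ PAH models from a cohort
#'
#' Classifies every record by PAH through the cut-off table, fits one OLS
#' model per maturity stage plus the pooled (general) model.
#'
#' @param cohort A `cohort_table` with `observed_sa_years` and the chosen
#'   PAH available for every record.
#' @param cutoffs Cut-off table used for stage classification.
#' @param pah_field `"tw3"` or `"kr"` (uses `pah_tw3` / `pah_kr`, falling
#'   back to computation from `adult_height_tw3_cm` or anthropometry).
#' @param kr_table Coefficient table when `pah_field = "kr"`.
#' @return A `staged_model_set` fitted from the data, with the per-record
#'   PAH and stage labels attached as attribute `classification`.
#' @export
fit_staged_models <- function(cohort, cutoffs = default_cutoff_table(),
                              pah_field = c("tw3", "kr"), kr_table = NULL) {
  pah_field <- match.arg(pah_field)
  if (pah_field == "kr" && is.null(kr_table)) kr_table <- default_kr_table()
  sa <- cohort$observed_sa_years
  if (is.null(sa) || any(is.na(sa))) {
    stop("every record must carry observed_sa_years to fit models")
  }
  pah <- vapply(seq_len(nrow(cohort)), function(i) {
    .record_pah(as.list(cohort[i, ]), pah_field, kr_table)
  }, numeric(1))
  grp <- suppressMessages(age_group(cohort$decimal_age))
  status <- classify_by_pah(grp, pah, cutoffs)

  fit_stage <- function(s) {
    sel <- status == s
    if (sum(sel) < 3) {
      stop(sprintf("stage '%s' has %d record(s) after classification; need >= 3",
                   s, sum(sel)))
    }
    fit_linear_model(pah[sel], sa[sel])
  }
  models <- staged_model_set(
    general = fit_linear_model(pah, sa),
    late = fit_stage("late"),
    on_time = fit_stage("on_time"),
    early = fit_stage("early")
  )
  attr(models, "classification") <- data.frame(
    athlete_id = cohort$athlete_id, pah = pah, age_group = grp,
    maturity_status = as.character(status), stringsAsFactors = FALSE
  )
  models
}
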