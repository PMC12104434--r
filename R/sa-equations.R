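# Skeletal-age prediction equations: SA as a linear function of the
# percentage of adult height, with a general (whole-sample) model and one
# model per maturity stage. The two-stage workflow classifies the athlete
# by PAH first, then applies the stage-specific equation.

#' Construct a linear SA ~ PAH model specification
#'
#' @param intercept Intercept in years.
#' @param slope Slope in years per PAH percent.
#' @param residual_sd Residual standard deviation (estimated error), years.
#' @param r Correlation coefficient (optional).
#' @param r_squared Coefficient of determination (optional).
#' @param se_intercept,se_slope Standard errors of the coefficients (optional).
#' @param n Sample size the model was fitted on (optional).
#' @return A `linear_model_spec` list.
#' @export
linear_model_spec <- function(intercept, slope, residual_sd = NA_real_,
                              r = NA_real_, r_squared = NA_real_,
                              se_intercept = NA_real_, se_slope = NA_real_,
                              n = NA_integer_) {
  stopifnot(is.finite(intercept), is.finite(slope))
  if (!is.na(residual_sd) && residual_sd < 0) stop("residual_sd must be >= 0")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must be in [0, 1]")
  }
  structure(list(intercept = intercept, slope = slope, residual_sd = residual_sd,
                 r = r, r_squared = r_squared, se_intercept = se_intercept,
                 se_slope = se_slope, n = n),
            class = "linear_model_spec")
}

#' @export
print.linear_model_spec <- function(x, ...) {
  cat(sprintf("SA ~ PAH linear model: SA = %.3f + %.3f * PAH", x$intercept, x$slope))
  if (!is.na(x$residual_sd)) cat(sprintf("  (residual sd %.3f y", x$residual_sd))
  if (!is.na(x$r_squared)) cat(sprintf(", R^2 %.3f", x$r_squared))
  if (!is.na(x$residual_sd)) cat(")")
  cat("\n")
  invisible(x)
}

#' Bundle general plus stage-specific models
#'
#' @param general,late,on_time,early `linear_model_spec` objects.
#' @return A `staged_model_set` list.
#' @export
staged_model_set <- function(general, late, on_time, early) {
  models <- list(general = general, late = late, on_time = on_time, early = early)
  for (m in models) stopifnot(inherits(m, "linear_model_spec"))
  structure(models, class = "staged_model_set")
}

#' Published SA prediction equations
#'
#' The general equation `SA = -17.043 + 0.336 * PAH` fitted on the whole
#' development sample (n = 570, R^2 0.93), and the stage-specific equations:
#' late `-18.445 + 0.348 * PAH`, on-time `-15.742 + 0.321 * PAH`, early
#' `-11.106 + 0.275 * PAH`, with their residual standard deviations and
#' coefficient standard errors.
#'
#' @return A `staged_model_set`.
#' @export
default_models <- function() {
  staged_model_set(
    general = linear_model_spec(-17.043, 0.336, residual_sd = 0.606,
                                r = 0.96, r_squared = 0.93,
                                se_intercept = 0.343, se_slope = 0.004, n = 570L),
    late = linear_model_spec(-18.445, 0.348, residual_sd = 0.599,
                             r = 0.93, r_squared = 0.87,
                             se_intercept = 0.976, se_slope = 0.012),
    on_time = linear_model_spec(-15.742, 0.321, residual_sd = 0.541,
                                r = 0.96, r_squared = 0.92,
                                se_intercept = 0.476, se_slope = 0.005),
    early = linear_model_spec(-11.106, 0.275, residual_sd = 0.426,
                              r = 0.97, r_squared = 0.94,
                              se_intercept = 0.554, se_slope = 0.006)
  )
}

#' Predict skeletal age from PAH
#'
#' Evaluates `intercept + slope * pah`, unrounded; rounding to display
#' precision is left to the reporting layer. The equations were fitted on
#' PAH roughly 78-99%, so values outside the plausible (50, 110) band abort
#' in strict mode and warn otherwise.
#'
#' @param pah Percentage of adult height.
#' @param model A `linear_model_spec`.
#' @param strict If `TRUE` (default), PAH outside (50, 110) is an error;
#'   otherwise a warning.
#' @return Predicted skeletal age in years.
#' @export
predict_sa <- function(pah, model, strict = TRUE) {
  stopifnot(inherits(model, "linear_model_spec"))
  out_of_band <- !is.finite(pah) | pah <= 50 | pah >= 110
  if (any(out_of_band)) {
    msg <- paste0("PAH value(s) outside the plausible (50, 110) band: ",
                  paste(utils::head(pah[out_of_band], 5), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  model$intercept + model$slope * pah
}

# PAH for one record by the chosen method.
.record_pah <- function(rec, pah_method, kr_table) {
  if (pah_method == "tw3") {
    if (!is.null(rec$pah_tw3) && !is.na(rec$pah_tw3)) return(rec$pah_tw3)
    if (!is.null(rec$adult_height_tw3_cm) && !is.na(rec$adult_height_tw3_cm)) {
      return(percent_adult_height(rec$stature_cm, rec$adult_height_tw3_cm))
    }
    stop("record lacks pah_tw3 and adult_height_tw3_cm; TW3-based PAH unavailable")
  }
  if (!is.null(rec$pah_kr) && !is.na(rec$pah_kr)) return(rec$pah_kr)
  if (is.null(kr_table)) kr_table <- default_kr_table()
  predict_adult_height_kr(rec, kr_table)$pah
}

#' Assess one athlete: classify, then predict skeletal age
#'
#' The two-stage workflow: compute PAH by the chosen method, assign the
#' integer age group, classify maturity status from the age-specific
#' cut-offs, then evaluate both the general equation and the equation for
#' the assigned stage.
#'
#' @param record One athlete record (list or one-row data.frame using the
#'   [cohort_schema()] fields).
#' @param models A `staged_model_set`; defaults to [default_models()].
#' @param cutoffs A cut-off table; defaults to [default_cutoff_table()].
#' @param pah_method `"tw3"` (uses `pah_tw3` or `adult_height_tw3_cm`) or
#'   `"kr"` (uses `pah_kr` or predicts adult height from anthropometry).
#' @param kr_table Coefficient table for the `"kr"` method; defaults to the
#'   shipped synthetic table.
#' @param strict Passed to [predict_sa()].
#' @return One-row data.frame: `athlete_id`, `age_group`, `pah_used`,
#'   `pah_method`, `maturity_status`, `sa_general`, `sa_staged`.
#' @export
assess_athlete <- function(record, models = default_models(),
                           cutoffs = default_cutoff_table(),
                           pah_method = c("tw3", "kr"), kr_table = NULL,
                           strict = TRUE) {
  pah_method <- match.arg(pah_method)
  rec <- as.list(record)
  pah <- .record_pah(rec, pah_method, kr_table)
  grp <- suppressMessages(age_group(rec$decimal_age))
  status <- classify_by_pah(grp, pah, cutoffs)
  data.frame(
    athlete_id = as.character(rec$athlete_id),
    age_group = grp,
    pah_used = pah,
    pah_method = pah_method,
    maturity_status = as.character(status),
    sa_general = predict_sa(pah, models$general, strict = strict),
    sa_staged = predict_sa(pah, models[[as.character(status)]], strict = strict),
    stringsAsFactors = FALSE
  )
}

#' Assess every athlete in a cohort
#'
#' @param cohort A `cohort_table`.
#' @inheritParams assess_athlete
#' @return A data.frame with one [assess_athlete()] row per record.
#' @export
assess_cohort <- function(cohort, models = default_models(),
                          cutoffs = default_cutoff_table(),
                          pah_method = c("tw3", "kr"), kr_table = NULL,
                          strict = TRUE) {
  pah_method <- match.arg(pah_method)
  if (pah_method == "kr" && is.null(kr_table)) kr_table <- default_kr_table()
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    assess_athlete(cohort[i, ], models = models, cutoffs = cutoffs,
                   pah_method = pah_method, kr_table = kr_table, strict = strict)
  })
  do.call(rbind, rows)
}

#' Write a staged model set to CSV
#'
#' One row per stage (`general`, `late`, `on_time`, `early`) with columns
#' `stage`, `intercept`, `slope`, `residual_sd`, `se_intercept`, `se_slope`,
#' `r`, `r_squared`, `n`.
#'
#' @param models A `staged_model_set`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_model_set <- function(models, path) {
  stopifnot(inherits(models, "staged_model_set"))
  rows <- do.call(rbind, lapply(names(models), function(s) {
    m <- models[[s]]
    data.frame(stage = s, intercept = m$intercept, slope = m$slope,
               residual_sd = m$residual_sd, se_intercept = m$se_intercept,
               se_slope = m$se_slope, r = m$r, r_squared = m$r_squared,
               n = m$n, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a staged model set from CSV
#'
#' @param path CSV path in the [write_model_set()] layout.
#' @return A `staged_model_set`.
#' @export
read_model_set <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("general", "late", "on_time", "early")
  miss <- setdiff(need, tab$stage)
  if (length(miss) > 0) stop("model CSV missing stage(s): ", paste(miss, collapse = ", "))
  get <- function(s) {
    r <- tab[tab$stage == s, ][1, ]
    opt <- function(f) if (f %in% names(r) && !is.na(r[[f]])) r[[f]] else NA_real_
    linear_model_spec(r$intercept, r$slope, residual_sd = opt("residual_sd"),
                      r = opt("r"), r_squared = opt("r_squared"),
                      se_intercept = opt("se_intercept"), se_slope = opt("se_slope"),
                      n = if ("n" %in% names(r)) r$n else NA_integer_)
  }
  staged_model_set(get("general"), get("late"), get("on_time"), get("early"))
}
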