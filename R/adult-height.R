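# Khamis-Roche style adult-height prediction: age-binned linear model on
# current stature (in), body mass (lb) and mid-parental stature (in).
# Coefficients live in an external, swappable CSV asset; the package ships a
# SYNTHETIC placeholder table so the toolkit's own logic is testable without
# the published coefficient values (install those separately if numerical
# agreement with the original method is required).

#' Mid-parental stature
#'
#' Arithmetic mean of the biological parents' standing statures.
#'
#' @param mother_cm,father_cm Parents' statures in cm, each in (100, 250).
#' @return Mid-parental stature in cm.
#' @export
midparent_stature <- function(mother_cm, father_cm) {
  for (v in list(mother_cm, father_cm)) {
    if (length(v) == 0 || any(is.na(v))) {
      stop("midparent_stature: both parental statures must be present")
    }
    if (any(v <= 100 | v >= 250)) {
      stop("midparent_stature: parental stature outside the plausible (100, 250) cm range")
    }
  }
  (mother_cm + father_cm) / 2
}

#' Load an adult-height coefficient table
#'
#' Reads a CSV with columns `age_lower`, `intercept`, `coeff_stature`,
#' `coeff_mass`, `coeff_midparent`. Rows are half-year age bins keyed by
#' their lower bound; the table must have strictly increasing, uniformly
#' spaced bins (contiguous coverage). Units are Khamis-Roche convention:
#' intercept and prediction in inches, stature and mid-parent in inches,
#' mass in pounds.
#'
#' @param path Path to the coefficient CSV.
#' @return A `kr_coefficient_table` data.frame, sorted by `age_lower`.
#' @export
load_kr_coefficients <- function(path) {
  if (!file.exists(path)) stop("coefficient file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_lower", "intercept", "coeff_stature", "coeff_mass", "coeff_midparent")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("coefficient CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab <- tab[, need]
  for (f in need) {
    v <- suppressWarnings(as.numeric(tab[[f]]))
    if (any(is.na(v))) stop("non-numeric value in coefficient column ", f)
    tab[[f]] <- v
  }
  tab <- tab[order(tab$age_lower), , drop = FALSE]
  if (anyDuplicated(tab$age_lower)) stop("duplicated age_lower bin in coefficient table")
  if (nrow(tab) > 1) {
    steps <- diff(tab$age_lower)
    if (any(abs(steps - 0.5) > 1e-9)) {
      stop("coefficient table bins must be contiguous half-year bins; ",
           "found gaps or overlaps in age_lower")
    }
  }
  attr(tab, "bin_width") <- 0.5
  rownames(tab) <- NULL
  class(tab) <- c("kr_coefficient_table", "data.frame")
  tab
}

#' Default (synthetic) adult-height coefficient table
#'
#' Loads the synthetic placeholder coefficient table shipped with the
#' package (`inst/extdata/kr_coefficients_synthetic.csv`). Its coefficients
#' are smooth and plausible in sign and magnitude but are NOT the published
#' Khamis-Roche values; replace via [load_kr_coefficients()] for production
#' use.
#'
#' @return A `kr_coefficient_table`.
#' @export
default_kr_table <- function() {
  load_kr_coefficients(system.file("extdata", "kr_coefficients_synthetic.csv",
                                   package = "skelage", mustWork = TRUE))
}

# Index of the age bin containing `age`: half-open [lower, next_lower),
# last bin closed on the right at lower + bin_width.
.kr_bin_index <- function(age, table) {
  lowers <- table$age_lower
  width <- attr(table, "bin_width")
  hi <- lowers[length(lowers)] + width
  if (age < lowers[1] || age > hi) {
    stop(sprintf("age %.2f outside the coefficient table span [%.1f, %.1f]",
                 age, lowers[1], hi))
  }
  min(findInterval(age, lowers), length(lowers))
}

#' Predict adult stature from current anthropometry
#'
#' Selects the age bin containing the athlete's decimal age and evaluates
#' the bin's linear model on current stature, body mass and mid-parental
#' stature (converted internally to inches/pounds).
#'
#' @param record One athlete record: a list or one-row data.frame with
#'   `decimal_age`, `stature_cm`, `body_mass_kg`, `mother_stature_cm`,
#'   `father_stature_cm`.
#' @param table A `kr_coefficient_table`; defaults to the shipped synthetic
#'   table.
#' @return List with `predicted_adult_height_cm`, `method = "kr"` and `pah`
#'   (percentage of adult height at observation).
#' @export
predict_adult_height_kr <- function(record, table = default_kr_table()) {
  rec <- as.list(record)
  mom <- rec$mother_stature_cm
  dad <- rec$father_stature_cm
  if (is.null(mom) || is.null(dad) || is.na(mom) || is.na(dad)) {
    stop("predict_adult_height_kr: parental statures unavailable for this record")
  }
  mp_in <- midparent_stature(mom, dad) / .CM_PER_INCH
  imp <- to_imperial(rec$stature_cm, rec$body_mass_kg)
  row <- table[.kr_bin_index(rec$decimal_age, table), ]
  pred_in <- row$intercept +
    row$coeff_stature * imp$stature_in +
    row$coeff_mass * imp$mass_lb +
    row$coeff_midparent * mp_in
  pred_cm <- pred_in * .CM_PER_INCH
  if (pred_cm <= 0) stop("predicted adult height is non-positive; check coefficients")
  list(
    predicted_adult_height_cm = pred_cm,
    method = "kr",
    pah = percent_adult_height(rec$stature_cm, pred_cm)
  )
}

#' Percentage of adult height
#'
#' `100 * current / adult`. Values above 100 are possible when the adult
#' height is under-predicted; they are reported as-is (a message flags them)
#' rather than clipped, so downstream skeletal-age predictions are not
#' silently distorted.
#'
#' @param current_cm Current stature in cm (positive).
#' @param adult_cm Predicted or known adult stature in cm (positive).
#' @return PAH in percent.
#' @export
percent_adult_height <- function(current_cm, adult_cm) {
  if (any(!is.finite(adult_cm)) || any(adult_cm <= 0)) {
    stop("adult height must be positive")
  }
  if (any(!is.finite(current_cm)) || any(current_cm <= 0)) {
    stop("current stature must be positive")
  }
  pah <- 100 * current_cm / adult_cm
  if (any(pah > 100)) {
    message("percent_adult_height: ", sum(pah > 100),
            " value(s) exceed 100% (current stature above predicted adult height)")
  }
  pah
}
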