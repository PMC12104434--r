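# Maturity classification: late / on-time / early from the skeletal-age vs
# chronological-age difference, or from PAH via age-specific cut-offs; plus
# age grouping and bio-band assignment.

.maturity_levels <- c("late", "on_time", "early")
.bioband_levels <- c("pre_pubertal", "early_pubertal", "growth_spurt", "post_pubertal")

#' Integer age group of a decimal age
#'
#' Rounds half-up to the nearest integer year, matching age-group bands
#' symmetric around integers (a "13 years" group holds ages 12.5-13.49).
#' Groups outside the validated 10-15 range are returned but flagged with a
#' message.
#'
#' @param decimal_age Decimal chronological age in years (positive).
#' @return Integer age group(s).
#' @export
age_group <- function(decimal_age) {
  if (any(!is.finite(decimal_age)) || any(decimal_age <= 0)) {
    stop("decimal_age must be positive")
  }
  g <- floor(decimal_age + 0.5)
  out_of_range <- g < 10 | g > 15
  if (any(out_of_range)) {
    message("age_group: ", sum(out_of_range),
            " value(s) outside the validated 10-15 year range")
  }
  as.integer(g)
}

#' Classify maturity status from the SA minus CA difference
#'
#' On-time when skeletal age is within +/- 1.0 year of chronological age
#' (boundary inclusive), late when more than 1.0 year behind, early when
#' more than 1.0 year ahead.
#'
#' @param sa Skeletal age in years (positive).
#' @param ca Chronological (decimal) age in years (positive).
#' @return Factor with levels `late`, `on_time`, `early`.
#' @export
classify_by_sa_difference <- function(sa, ca) {
  if (any(!is.finite(sa)) || any(sa <= 0) || any(!is.finite(ca)) || any(ca <= 0)) {
    stop("sa and ca must be positive")
  }
  d <- sa - ca
  lab <- ifelse(d < -1.0, "late", ifelse(d > 1.0, "early", "on_time"))
  factor(lab, levels = .maturity_levels)
}

#' Classify maturity status from PAH via an age-specific cut-off table
#'
#' On-time is the open interval between the age group's inferior and
#' superior cut-offs; a PAH at or below the inferior cut-off is late, at or
#' above the superior cut-off early.
#'
#' @param age_grp Integer age group(s) present in `table`.
#' @param pah Percentage of adult height.
#' @param table A cut-off table; defaults to [default_cutoff_table()].
#' @return Factor with levels `late`, `on_time`, `early`.
#' @export
classify_by_pah <- function(age_grp, pah, table = default_cutoff_table()) {
  idx <- match(age_grp, table$age_group)
  if (any(is.na(idx))) {
    stop("age group(s) ", paste(unique(age_grp[is.na(idx)]), collapse = ", "),
         " absent from cut-off table; available: ",
         paste(table$age_group, collapse = ", "))
  }
  inf <- table$inferior_cutoff[idx]
  sup <- table$superior_cutoff[idx]
  lab <- ifelse(pah <= inf, "late", ifelse(pah >= sup, "early", "on_time"))
  factor(lab, levels = .maturity_levels)
}

#' Published age-specific PAH cut-off table
#'
#' Per-age inferior (late vs rest) and superior (early vs rest) PAH
#' thresholds for male soccer players aged 10-15, with the ROC metadata
#' (area under the curve with confidence interval, sensitivity and
#' specificity) attached for each side.
#'
#' @return A `cutoff_table` data.frame keyed by `age_group`.
#' @export
default_cutoff_table <- function() {
  tab <- data.frame(
    age_group = 10:15,
    inferior_cutoff = c(78.3, 81.1, 84.5, 86.7, 91.1, 93.8),
    superior_cutoff = c(80.6, 84.3, 87.1, 91.3, 96.6, 99.0),
    auc_late = c(0.71, 0.90, 0.87, 0.97, 0.91, 0.98),
    auc_late_ci_low = c(0.59, 0.84, 0.79, 0.94, 0.81, 0.95),
    auc_late_ci_high = c(0.83, 0.95, 0.95, 1.00, 1.00, 1.00),
    sens_late = c(0.80, 0.87, 0.84, 0.95, 0.87, 0.91),
    spec_late = c(0.45, 0.72, 0.76, 0.89, 0.80, 1.00),
    auc_early = c(0.82, 0.97, 0.91, 0.94, 0.99, 0.96),
    auc_early_ci_low = c(0.51, 0.95, 0.85, 0.89, 0.98, 0.91),
    auc_early_ci_high = c(1.00, 0.99, 0.97, 0.98, 1.00, 1.00),
    sens_early = c(0.75, 0.86, 0.82, 0.76, 0.95, 0.85),
    spec_early = c(0.94, 0.94, 0.82, 0.93, 0.98, 0.93)
  )
  class(tab) <- c("cutoff_table", "data.frame")
  tab
}

.validate_cutoff_table <- function(tab) {
  if (anyDuplicated(tab$age_group)) stop("cut-off table has duplicated age groups")
  both <- !is.na(tab$inferior_cutoff) & !is.na(tab$superior_cutoff)
  if (any(tab$inferior_cutoff[both] >= tab$superior_cutoff[both])) {
    stop("cut-off table violates inferior < superior")
  }
  invisible(tab)
}

#' Read a cut-off table from CSV
#'
#' Requires columns `age_group`, `inferior_cutoff`, `superior_cutoff`;
#' any additional metadata columns are kept.
#'
#' @param path CSV path.
#' @return A `cutoff_table`.
#' @export
read_cutoff_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_group", "inferior_cutoff", "superior_cutoff")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("cut-off CSV missing column(s): ", paste(miss, collapse = ", "))
  tab <- tab[order(tab$age_group), , drop = FALSE]
  rownames(tab) <- NULL
  .validate_cutoff_table(tab)
  class(tab) <- c("cutoff_table", "data.frame")
  tab
}

#' Write a cut-off table to CSV
#'
#' @param table A `cutoff_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cutoff_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Bio-band from percentage of adult height
#'
#' Maturity bio-bands used to group young athletes by somatic maturity:
#' pre-pubertal below 85% of adult height, early pubertal in \[85, 90),
#' growth spurt (circa peak height velocity) in \[90, 96\], post-pubertal
#' above 96%.
#'
#' @param pah Percentage of adult height (positive).
#' @return Factor with levels `pre_pubertal`, `early_pubertal`,
#'   `growth_spurt`, `post_pubertal`.
#' @export
bioband_of_pah <- function(pah) {
  if (any(!is.finite(pah)) || any(pah <= 0)) stop("pah must be positive")
  lab <- ifelse(pah < 85, "pre_pubertal",
         ifelse(pah < 90, "early_pubertal",
         ifelse(pah <= 96, "growth_spurt", "post_pubertal")))
  factor(lab, levels = .bioband_levels)
}
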