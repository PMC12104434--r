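#' @keywords internal
"_PACKAGE"

# Fixed cohort CSV schema. The file layout is a package convention: the
# quantities (decimal age, stature, body mass, parents' statures, observed
# skeletal age, TW3-predicted adult height) are standard in maturity
# assessment, but no standard file format exists for them.
.cohort_mandatory <- c("athlete_id", "decimal_age", "stature_cm", "body_mass_kg")
.cohort_optional <- c(
  "mother_stature_cm", "father_stature_cm",
  "observed_sa_years", "adult_height_tw3_cm", "pah_tw3", "pah_kr"
)

#' Column names of the cohort CSV schema
#'
#' @return Named list with `mandatory` and `optional` character vectors.
#' @export
cohort_schema <- function() {
  list(mandatory = .cohort_mandatory, optional = .cohort_optional)
}

# Per-row invariant check; returns character(0) when valid, else reasons.
.validate_record <- function(row) {
  bad <- character(0)
  num <- function(f) suppressWarnings(as.numeric(row[[f]]))
  if (is.na(row[["athlete_id"]]) || !nzchar(row[["athlete_id"]])) {
    bad <- c(bad, "athlete_id empty")
  }
  for (f in c("decimal_age", "stature_cm", "body_mass_kg")) {
    v <- num(f)
    if (is.na(v) || v <= 0) bad <- c(bad, sprintf("%s must be a positive number", f))
  }
  for (f in c("mother_stature_cm", "father_stature_cm")) {
    v <- num(f)
    if (!is.na(v) && (v <= 100 || v >= 250)) {
      bad <- c(bad, sprintf("%s outside (100, 250) cm", f))
    }
  }
  sa <- num("observed_sa_years")
  if (!is.na(sa) && (sa <= 0 || sa >= 25)) {
    bad <- c(bad, "observed_sa_years outside (0, 25) years")
  }
  ah <- num("adult_height_tw3_cm")
  if (!is.na(ah) && ah <= 0) bad <- c(bad, "adult_height_tw3_cm must be positive")
  bad
}

#' Read a growth cohort from CSV
#'
#' Reads tabular growth records (one athlete observation per row) using the
#' fixed column schema of [cohort_schema()]. Mandatory columns are
#' `athlete_id`, `decimal_age`, `stature_cm`, `body_mass_kg`; the optional
#' columns carry parents' statures, observed skeletal age, the TW3-predicted
#' adult height and pre-computed percentage-of-adult-height values.
#'
#' @param path Path to a CSV file (comma delimiter, `.` decimal separator,
#'   UTF-8, header row required).
#' @param strict If `TRUE` (default) any row violating a record invariant
#'   aborts with an error naming the row; if `FALSE` offending rows are
#'   dropped and reported via [message()] and the `rejected` attribute.
#' @return A `cohort_table`: a `data.frame` with one row per athlete record,
#'   attributes `provenance` (source path) and, in lenient mode, `rejected`
#'   (a data.frame of dropped row indices and reasons).
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  missing_cols <- setdiff(.cohort_mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  keep <- intersect(c(.cohort_mandatory, .cohort_optional), names(raw))
  raw <- raw[, keep, drop = FALSE]
  for (f in setdiff(.cohort_optional, names(raw))) raw[[f]] <- NA_character_
  raw <- raw[, c(.cohort_mandatory, .cohort_optional), drop = FALSE]

  reasons <- lapply(seq_len(nrow(raw)), function(i) .validate_record(raw[i, ]))
  bad_idx <- which(lengths(reasons) > 0)
  if (length(bad_idx) > 0) {
    msgs <- vapply(bad_idx, function(i) {
      sprintf("row %d: %s", i, paste(reasons[[i]], collapse = "; "))
    }, character(1))
    if (strict) {
      stop("invalid cohort record(s):\n", paste(msgs, collapse = "\n"))
    }
    message("read_cohort: dropped ", length(bad_idx), " invalid row(s):\n",
            paste(msgs, collapse = "\n"))
  }
  ok <- setdiff(seq_len(nrow(raw)), bad_idx)
  out <- raw[ok, , drop = FALSE]
  for (f in setdiff(names(out), "athlete_id")) {
    out[[f]] <- suppressWarnings(as.numeric(out[[f]]))
  }
  if (anyDuplicated(out$athlete_id)) {
    stop("athlete_id values are not unique: ",
         paste(unique(out$athlete_id[duplicated(out$athlete_id)]), collapse = ", "))
  }
  rownames(out) <- NULL
  attr(out, "provenance") <- path
  if (length(bad_idx) > 0) {
    attr(out, "rejected") <- data.frame(
      row = bad_idx,
      reason = vapply(reasons[bad_idx], paste, character(1), collapse = "; "),
      stringsAsFactors = FALSE
    )
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write a cohort table to CSV
#'
#' @param cohort A `cohort_table` or compatible data.frame.
#' @param path Output path.
#' @return The number of data rows written, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- intersect(c(.cohort_mandatory, .cohort_optional), names(cohort))
  utils::write.csv(as.data.frame(cohort)[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(nrow(cohort))
}

#' Write athlete assessment results to CSV
#'
#' Emits the standard assessment layout: `athlete_id`, `age_group`, `pah`,
#' `maturity_status`, `predicted_sa_general`, `predicted_sa_staged`.
#'
#' @param rows A data.frame of assessment results as returned by
#'   [assess_cohort()] (columns `athlete_id`, `age_group`, `pah_used`,
#'   `maturity_status`, `sa_general`, `sa_staged`), or an empty data.frame.
#' @param path Output path.
#' @param digits Decimal places for numeric columns (default 2).
#' @return Number of data rows written.
#' @export
write_assessments <- function(rows, path, digits = 2) {
  stopifnot(is.numeric(digits), digits >= 0)
  out <- data.frame(
    athlete_id = character(0), age_group = numeric(0), pah = numeric(0),
    maturity_status = character(0), predicted_sa_general = numeric(0),
    predicted_sa_staged = numeric(0), stringsAsFactors = FALSE
  )
  if (nrow(rows) > 0) {
    rnd <- function(x) round(as.numeric(x), digits)
    out <- data.frame(
      athlete_id = as.character(rows$athlete_id),
      age_group = rows$age_group,
      pah = rnd(rows$pah_used),
      maturity_status = as.character(rows$maturity_status),
      predicted_sa_general = rnd(rows$sa_general),
      predicted_sa_staged = rnd(rows$sa_staged),
      stringsAsFactors = FALSE
    )
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) stop("cannot write assessments to ", path, ": ",
                              conditionMessage(e)))
  nrow(out)
}

.CM_PER_INCH <- 2.54
.LB_PER_KG <- 2.20462262185

#' Metric to imperial unit conversion
#'
#' Khamis-Roche coefficients are defined on inches and pounds; all public
#' interfaces of this package use cm and kg, with this conversion applied
#' internally.
#'
#' @param stature_cm Stature in centimetres (positive).
#' @param mass_kg Body mass in kilograms (positive).
#' @return List with `stature_in` (inches) and `mass_lb` (pounds).
#' @export
to_imperial <- function(stature_cm, mass_kg) {
  if (any(!is.finite(stature_cm)) || any(stature_cm <= 0) ||
      any(!is.finite(mass_kg)) || any(mass_kg <= 0)) {
    stop("stature and mass must be positive finite numbers")
  }
  list(stature_in = stature_cm / .CM_PER_INCH, mass_lb = mass_kg * .LB_PER_KG)
}

#' Imperial to metric unit conversion (inverse of [to_imperial()])
#'
#' @param stature_in Stature in inches (positive).
#' @param mass_lb Body mass in pounds (positive).
#' @return List with `stature_cm` and `mass_kg`.
#' @export
to_metric <- function(stature_in, mass_lb) {
  if (any(!is.finite(stature_in)) || any(stature_in <= 0) ||
      any(!is.finite(mass_lb)) || any(mass_lb <= 0)) {
    stop("stature and mass must be positive finite numbers")
  }
  list(stature_cm = stature_in * .CM_PER_INCH, mass_kg = mass_lb / .LB_PER_KG)
}
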