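#' Ordered BMI group labels
#'
#' @return Character vector of the four weight-status groups, lightest first.
#' @export
bmi_groups <- function() c("underweight", "normal", "overweight", "obese")

#' Validate a BMI cut-off table
#'
#' A cut-off table holds age- and sex-specific BMI thresholds separating
#' the four weight-status groups, in the style of the IOTF (Cole et al.)
#' reference tables. Required columns: `age_years`, `sex` ("boy"/"girl"),
#' `underweight_cutoff`, `overweight_cutoff`, `obese_cutoff` (kg/m^2).
#' Within each row the three cut-offs must be strictly increasing and ages
#' must be strictly increasing within each sex.
#'
#' @param table A data frame with the columns above.
#' @return The validated table, invisibly classed `bmi_cutoff_table`.
#' @export
bmi_cutoff_table <- function(table) {
  req <- c("age_years", "sex", "underweight_cutoff",
           "overweight_cutoff", "obese_cutoff")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols) > 0L) {
    stop("cut-off table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(table$sex %in% c("boy", "girl"))) {
    stop("cut-off table sex must be 'boy' or 'girl'", call. = FALSE)
  }
  bad <- with(table, !(underweight_cutoff < overweight_cutoff &
                         overweight_cutoff < obese_cutoff))
  if (any(bad)) {
    stop("cut-offs must increase underweight < overweight < obese in every row",
         call. = FALSE)
  }
  for (s in unique(table$sex)) {
    ages <- table$age_years[table$sex == s]
    if (is.unsorted(ages, strictly = TRUE)) {
      stop("ages must be strictly increasing within sex '", s, "'",
           call. = FALSE)
    }
  }
  structure(as.data.frame(table), class = c("bmi_cutoff_table", "data.frame"))
}

#' Default BMI cut-off table (synthetic)
#'
#' Loads the IOTF-style cut-off table shipped with the package. The values
#' are a smooth synthetic stand-in for the published age- and sex-specific
#' reference cut-offs (which this package deliberately treats as external
#' configuration): they follow the characteristic U-shape with the
#' adiposity-rebound minimum near age 5--6 and pass through the adult
#' anchor points 17 / 25 / 30 kg/m^2 at age 18. Substitute the published
#' tables via [bmi_cutoff_table()] for work against real cohorts.
#'
#' @return A `bmi_cutoff_table`.
#' @export
default_bmi_cutoffs <- function() {
  path <- system.file("extdata", "bmi_cutoffs_synthetic.csv",
                      package = "pepower", mustWork = TRUE)
  bmi_cutoff_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

# Interpolate the three cut-offs to an exact age for one sex.
# Linear interpolation between adjacent table rows (the reference tables
# are printed at half- or whole-year steps); ages outside the table are an
# error, not an extrapolation.
cutoffs_at <- function(age, sex, table) {
  stopifnot(inherits(table, "bmi_cutoff_table"))
  out <- matrix(NA_real_, nrow = length(age), ncol = 3L,
                dimnames = list(NULL, c("underweight", "overweight", "obese")))
  for (s in unique(sex)) {
    idx <- sex == s
    sub <- table[table$sex == s, , drop = FALSE]
    if (nrow(sub) < 2L) {
      stop("cut-off table has fewer than 2 rows for sex '", s, "'",
           call. = FALSE)
    }
    a <- age[idx]
    if (any(a < min(sub$age_years) | a > max(sub$age_years))) {
      stop("age outside the cut-off table range [", min(sub$age_years), ", ",
           max(sub$age_years), "] for sex '", s, "'", call. = FALSE)
    }
    out[idx, "underweight"] <-
      stats::approx(sub$age_years, sub$underweight_cutoff, xout = a)$y
    out[idx, "overweight"] <-
      stats::approx(sub$age_years, sub$overweight_cutoff, xout = a)$y
    out[idx, "obese"] <-
      stats::approx(sub$age_years, sub$obese_cutoff, xout = a)$y
  }
  out
}

#' Classify BMI into weight-status groups
#'
#' Assigns each observation to underweight / normal / overweight / obese by
#' comparing BMI against the age- and sex-specific cut-offs, interpolated
#' linearly to the exact age. Intervals are half-open `[lower, upper)`: a
#' BMI exactly at a cut-off belongs to the heavier side, so e.g. a value
#' equal to the underweight cut-off is classified normal.
#'
#' @param bmi BMI in kg/m^2.
#' @param age Age in years (must lie within the table's age range).
#' @param sex `"boy"` or `"girl"` (recycled if length 1).
#' @param table A [bmi_cutoff_table()]; default [default_bmi_cutoffs()].
#' @return Factor with levels [bmi_groups()].
#' @export
classify_bmi <- function(bmi, age, sex, table = default_bmi_cutoffs()) {
  stopifnot(is.numeric(bmi), is.numeric(age))
  n <- length(bmi)
  if (length(age) == 1L) age <- rep(age, n)
  if (length(sex) == 1L) sex <- rep(sex, n)
  stopifnot(length(age) == n, length(sex) == n)
  if (!all(sex %in% c("boy", "girl"))) {
    stop("sex must be 'boy' or 'girl'", call. = FALSE)
  }
  cuts <- cutoffs_at(age, sex, table)
  grp <- ifelse(bmi < cuts[, "underweight"], "underweight",
         ifelse(bmi < cuts[, "overweight"],  "normal",
         ifelse(bmi < cuts[, "obese"],       "overweight", "obese")))
  factor(grp, levels = bmi_groups())
}
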