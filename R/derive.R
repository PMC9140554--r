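#' Derive per-subject field-test metrics
#'
#' Turns raw subject records (flight times or a best jump height) into the
#' analysis table: best CMJ height, BMI and BMI group, the potential-energy
#' index under both conventions, and peak power from each configured linear
#' equation. Subjects with no valid jump trial are dropped with a message.
#'
#' @param records Data frame with columns `id`, `sex` ("boy"/"girl"),
#'   `age_years`, `height_cm`, `mass_kg`, and either flight-time columns
#'   `ft1_s`..`ft3_s` (seconds) or a best jump height `cmj_cm` (cm).
#' @param cutoffs A [bmi_cutoff_table()] for weight-status classification.
#' @param equations Named list of [power_equation()]s; the default supplies
#'   `duncan` and `gomez` (see [power_equations()]). Each contributes a
#'   `pp_<name>_W` column.
#' @param g Gravitational acceleration in m/s^2.
#' @return Data frame with columns `id`, `sex`, `age_years`, `height_cm`,
#'   `mass_kg`, `cmj_cm`, `bmi`, `bmi_group`, `pe_operational`,
#'   `pe_physical_J`, and one `pp_<name>_W` per equation.
#' @export
derive_metrics <- function(records,
                           cutoffs = default_bmi_cutoffs(),
                           equations = power_equations(),
                           g = 9.79) {
  req <- c("id", "sex", "age_years", "height_cm", "mass_kg")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L) {
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ft_cols <- intersect(c("ft1_s", "ft2_s", "ft3_s"), names(records))
  has_ft <- length(ft_cols) > 0L
  if (!has_ft && !("cmj_cm" %in% names(records))) {
    stop("records need flight-time columns (ft1_s..ft3_s) or cmj_cm",
         call. = FALSE)
  }
  if (any(records$height_cm <= 0) || any(records$mass_kg <= 0)) {
    stop("height and mass must be positive", call. = FALSE)
  }

  if (has_ft) {
    ft <- as.matrix(records[, ft_cols, drop = FALSE])
    valid <- rowSums(!is.na(ft)) > 0L
    if (any(!valid)) {
      message("dropping ", sum(!valid), " subject(s) with no valid jump trial")
      records <- records[valid, , drop = FALSE]
      ft <- ft[valid, , drop = FALSE]
    }
    heights_m <- flight_time_to_height(ft, g)
    cmj_cm <- 100 * apply(heights_m, 1L, max, na.rm = TRUE)
  } else {
    cmj_cm <- records$cmj_cm
    if (any(is.na(cmj_cm))) {
      message("dropping ", sum(is.na(cmj_cm)), " subject(s) with no jump height")
      records <- records[!is.na(records$cmj_cm), , drop = FALSE]
      cmj_cm <- records$cmj_cm
    }
  }

  bmi <- compute_bmi(records$mass_kg, records$height_cm)
  out <- data.frame(
    id = records$id,
    sex = records$sex,
    age_years = records$age_years,
    height_cm = records$height_cm,
    mass_kg = records$mass_kg,
    cmj_cm = cmj_cm,
    bmi = bmi,
    bmi_group = classify_bmi(bmi, records$age_years, records$sex, cutoffs),
    pe_operational = potential_energy(records$mass_kg, cmj_cm / 100,
                                      convention = "operational"),
    pe_physical_J = potential_energy(records$mass_kg, cmj_cm / 100, g,
                                     convention = "physical"),
    stringsAsFactors = FALSE
  )
  for (nm in names(equations)) {
    out[[paste0("pp_", nm, "_W")]] <-
      peak_power(equations[[nm]], cmj_cm, records$mass_kg)
  }
  out
}
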