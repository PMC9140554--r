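#' Synthetic cohort configuration
#'
#' Parameters of the synthetic anthropometric cohort generator. The
#' defaults reproduce the structure of the study sample's descriptive
#' table: 815 children, 51% girls, ages 6--11, four BMI groups with
#' proportions 40/431/216/128 out of 815, and the per-group body-mass and
#' CMJ-height means and SDs printed there (two per-group age SDs are
#' printed as "16"/"15"; the calibration presumes the plausible 1.6/1.5,
#' though per-group age moments are not generator inputs).
#'
#' @param n_subjects Number of children (>= 1).
#' @param prop_girls Proportion of girls in \[0, 1\].
#' @param age_range Two ages in years; ages are drawn uniformly on this
#'   interval, so `c(6, 12)` emulates "aged 6--11".
#' @param group_weights Four non-negative BMI-group proportions
#'   (underweight, normal, overweight, obese) summing to 1.
#' @param mass_mean,mass_sd Per-group body-mass mean/SD in kg (length 4).
#' @param cmj_mean,cmj_sd Per-group best-CMJ-height mean/SD in cm (length 4).
#' @param height_mean,height_sd Target marginal height in cm. Heights are
#'   solved from mass and a group-consistent BMI rather than drawn, so
#'   these describe the intended marginal and are used only for sanity
#'   checks and documentation.
#' @param trial_jitter_sd SD in cm of the trial-to-trial jitter applied
#'   around each child's best jump so that "best of three" is meaningful.
#' @param rng_seed Integer seed controlling all randomness in
#'   [generate_cohort()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 815L,
                          prop_girls = 416 / 815,
                          age_range = c(6, 12),
                          group_weights = c(40, 431, 216, 128) / 815,
                          mass_mean = c(25.5, 30.7, 41.0, 48.2),
                          mass_sd = c(4.6, 6.9, 9.5, 12.0),
                          cmj_mean = c(26.2, 25.3, 22.8, 19.8),
                          cmj_sd = c(5.8, 5.7, 5.3, 4.5),
                          height_mean = 136.7,
                          height_sd = 11.8,
                          trial_jitter_sd = 0.5,
                          rng_seed = 1L) {
  cfg <- list(n_subjects = n_subjects, prop_girls = prop_girls,
              age_range = age_range, group_weights = group_weights,
              mass_mean = mass_mean, mass_sd = mass_sd,
              cmj_mean = cmj_mean, cmj_sd = cmj_sd,
              height_mean = height_mean, height_sd = height_sd,
              trial_jitter_sd = trial_jitter_sd, rng_seed = rng_seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid cohort configuration: field '", field, "' ", why,
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_subjects) || length(cfg$n_subjects) != 1L ||
      cfg$n_subjects < 1) fail("n_subjects", "must be a count >= 1")
  if (!is.numeric(cfg$prop_girls) || cfg$prop_girls < 0 || cfg$prop_girls > 1)
    fail("prop_girls", "must lie in [0, 1]")
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) <= 0)
    fail("age_range", "must be an increasing pair of ages")
  if (length(cfg$group_weights) != 4L || any(cfg$group_weights < 0))
    fail("group_weights", "must be 4 non-negative fractions")
  if (abs(sum(cfg$group_weights) - 1) > 1e-12)
    fail("group_weights", "must sum to 1")
  for (f in c("mass_mean", "mass_sd", "cmj_mean", "cmj_sd")) {
    if (length(cfg[[f]]) != 4L) fail(f, "must have length 4")
  }
  for (f in c("mass_sd", "cmj_sd")) {
    if (any(cfg[[f]] <= 0)) fail(f, "SDs must be > 0")
  }
  if (cfg$height_sd <= 0) fail("height_sd", "must be > 0")
  if (cfg$trial_jitter_sd < 0) fail("trial_jitter_sd", "must be >= 0")
  invisible(cfg)
}

#' Generate a synthetic anthropometric cohort
#'
#' Draws a cohort with the joint structure needed downstream: each child
#' gets a BMI group, then a body mass from the group's truncated-normal
#' distribution, then a BMI drawn uniformly inside the group's BMI interval
#' at the child's age and sex (so the label is consistent with the
#' generated mass and height by construction), a standing height solved
#' from mass and BMI, a best CMJ height from the group's truncated-normal
#' distribution, and three flight times back-solved from jittered trial
#' heights whose maximum equals the best height exactly.
#'
#' @param config A [cohort_config()].
#' @param cutoffs A [bmi_cutoff_table()] defining the group BMI intervals;
#'   default [default_bmi_cutoffs()].
#' @param g Gravitational acceleration in m/s^2 used to back-solve flight
#'   times.
#' @return Data frame with columns `id`, `sex` ("boy"/"girl"),
#'   `age_years`, `height_cm`, `mass_kg`, `ft1_s`, `ft2_s`, `ft3_s`, and
#'   the intended `bmi_group` (redundant with downstream classification,
#'   kept for convenience; not part of the file schema).
#' @export
generate_cohort <- function(config = cohort_config(),
                            cutoffs = default_bmi_cutoffs(),
                            g = 9.79) {
  stopifnot(inherits(config, "cohort_config") || is.list(config))
  validate_cohort_config(config)
  n <- as.integer(config$n_subjects)
  set.seed(config$rng_seed)

  grp <- sample.int(4L, n, replace = TRUE, prob = config$group_weights)
  sex <- ifelse(stats::runif(n) < config$prop_girls, "girl", "boy")
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  mass <- rtruncnorm_pos(n, config$mass_mean[grp], config$mass_sd[grp])

  # group BMI interval at each child's age/sex; the underweight floor and
  # obese ceiling widths are fixed so the group BMI means land near the
  # calibration table's 13.6 / 16.6 / 20.7 / 24.8 kg/m^2
  cuts <- cutoffs_at(age, sex, cutoffs)
  lo <- cbind(cuts[, "underweight"] - 1.2, cuts[, "underweight"],
              cuts[, "overweight"], cuts[, "obese"])
  hi <- cbind(cuts[, "underweight"], cuts[, "overweight"],
              cuts[, "obese"], cuts[, "obese"] + 5.0)
  bmi <- stats::runif(n, lo[cbind(seq_len(n), grp)], hi[cbind(seq_len(n), grp)])
  height_cm <- 100 * sqrt(mass / bmi)

  best_cmj_cm <- rtruncnorm_pos(n, config$cmj_mean[grp], config$cmj_sd[grp])
  # three trial heights; shifting the jitter so its maximum is zero makes
  # the best-of-three equal best_cmj_cm exactly
  dev <- matrix(stats::rnorm(3L * n, 0, config$trial_jitter_sd), nrow = n)
  dev <- dev - apply(dev, 1L, max)
  trial_cm <- pmax(best_cmj_cm + dev, 0.5)
  ft <- height_to_flight_time(trial_cm / 100, g)

  data.frame(
    id = sprintf("S%04d", seq_len(n)),
    sex = sex,
    age_years = age,
    height_cm = height_cm,
    mass_kg = mass,
    ft1_s = ft[, 1L], ft2_s = ft[, 2L], ft3_s = ft[, 3L],
    bmi_group = factor(bmi_groups()[grp], levels = bmi_groups()),
    stringsAsFactors = FALSE
  )
}

cohort_schema <- c("id", "sex", "age_years", "height_cm", "mass_kg",
                   "ft1_s", "ft2_s", "ft3_s")

#' Write / read a cohort CSV
#'
#' The file schema is `id,sex,age_years,height_cm,mass_kg,ft1_s,ft2_s,ft3_s`
#' with sex coded "boy"/"girl"; numeric coding is applied downstream.
#'
#' @param cohort A cohort data frame (extra columns are dropped on write).
#' @param path File path.
#' @return `read_cohort` returns the validated data frame.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(cohort_schema, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(cohort[, cohort_schema], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_schema, names(x))
  if (length(missing_cols) > 0L) {
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(x$sex %in% c("boy", "girl"))) {
    stop("cohort file sex must be coded 'boy'/'girl'", call. = FALSE)
  }
  x
}
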