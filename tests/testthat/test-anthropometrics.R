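test_that("flight time converts to height by the ballistic formula", {
  expect_equal(flight_time_to_height(0), 0)
  expect_equal(flight_time_to_height(0.441, g = 9.79), 9.79 * 0.441^2 / 8,
               tolerance = 1e-12)
  expect_equal(round(flight_time_to_height(0.441, g = 9.79), 4), 0.2380)
  expect_error(flight_time_to_height(-0.1), "non-negative")
  # strictly increasing in t
  t <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(flight_time_to_height(t)) > 0))
})

test_that("height/flight-time conversion round-trips", {
  h <- 0.198
  t <- height_to_flight_time(h)
  expect_equal(round(t, 4), 0.4022)
  expect_equal(flight_time_to_height(t), h, tolerance = 1e-12)
  hs <- runif(50, 0.05, 0.6)
  expect_equal(flight_time_to_height(height_to_flight_time(hs)), hs,
               tolerance = 1e-10)
})

test_that("best trial takes the maximum over non-missing trials", {
  expect_equal(best_trial(c(0.21, 0.24, 0.22)), 0.24)
  expect_equal(best_trial(0.24), 0.24)
  expect_equal(best_trial(c(0.24, 0.24, 0.20)), 0.24)
  expect_equal(best_trial(c(NA, 0.19, NA)), 0.19)
  expect_error(best_trial(c(NA_real_, NA_real_)), "missing")
})

test_that("potential energy follows both conventions, differing exactly by g", {
  # whole-sample means of the calibration table: printed index value 8.5
  expect_equal(round(potential_energy(35.9, 0.238), 1), 8.5)
  expect_equal(potential_energy(35.9, 0.238, convention = "physical"),
               35.9 * 9.79 * 0.238, tolerance = 1e-12)
  expect_equal(potential_energy(35.9, 0.238, convention = "physical"), 83.65,
               tolerance = 1e-3)
  expect_equal(potential_energy(40, 0), 0)
  expect_equal(potential_energy(40, 0, convention = "physical"), 0)
  expect_error(potential_energy(0, 0.2), "positive")
  # ratio invariant for arbitrary positive inputs
  m <- runif(20, 20, 60); h <- runif(20, 0.05, 0.5)
  expect_equal(potential_energy(m, h, g = 9.79, convention = "physical") /
                 potential_energy(m, h, convention = "operational"),
               rep(9.79, 20), tolerance = 1e-12)
  # strictly increasing in each argument
  expect_true(all(diff(potential_energy(seq(20, 60, 5), 0.3)) > 0))
  expect_true(all(diff(potential_energy(30, seq(0.1, 0.5, 0.05))) > 0))
})

test_that("peak power is the configured linear form", {
  eq_unit <- power_equation("unit", 1, 1, 0)
  expect_equal(peak_power(eq_unit, 23.8, 35.9), 59.7)
  eq_const <- power_equation("const", 0, 0, 123.4)
  expect_equal(peak_power(eq_const, 10, 50), 123.4)
  expect_equal(peak_power(eq_const, 40, 20), 123.4)
  # metre-unit equations convert the cm input internally
  eq_m <- power_equation("metres", 100, 0, 0, height_unit = "m")
  expect_equal(peak_power(eq_m, 25, 0), 25)
})

test_that("default power equations reproduce the calibration group means", {
  eqs <- power_equations()
  # group means of a linear equation are the equation at the group means
  h <- c(23.8, 26.2, 25.3, 22.8, 19.8)
  m <- c(35.9, 25.5, 30.7, 41.0, 48.2)
  pp_d <- c(922.7, 743.9, 852.9, 1027.9, 1035.8)
  pp_g <- c(1007.0, 776.1, 909.9, 1124.5, 1207.6)
  expect_equal(peak_power(eqs$duncan, h, m), pp_d, tolerance = 5 / 900)
  expect_equal(peak_power(eqs$gomez, h, m), pp_g, tolerance = 5 / 900)
})

test_that("BMI is mass over squared height in metres", {
  expect_equal(compute_bmi(1, 100), 1.0)
  expect_equal(round(compute_bmi(48.2, 138.1), 2), 25.27)
  expect_error(compute_bmi(16, 0), "positive")
})

test_that("BMI classification uses half-open age-interpolated intervals", {
  tab <- toy_cutoffs()
  expect_equal(as.character(classify_bmi(13.9, 8, "boy", tab)), "underweight")
  expect_equal(as.character(classify_bmi(14.0, 8, "boy", tab)), "normal")
  expect_equal(as.character(classify_bmi(18.5, 8, "boy", tab)), "overweight")
  expect_equal(as.character(classify_bmi(21.5, 8, "boy", tab)), "obese")
  expect_error(classify_bmi(17, 25, "boy", tab), "outside")
})

test_that("classification is monotone in BMI and partitions the line", {
  set.seed(42)
  for (rep in 1:10) {
    base <- sort(runif(3, 12, 30))
    tab <- bmi_cutoff_table(data.frame(
      age_years = rep(c(3, 16), each = 2), sex = rep(c("boy", "girl"), 2),
      underweight_cutoff = base[1], overweight_cutoff = base[2],
      obese_cutoff = base[3]))
    bmi <- sort(runif(60, 10, 35))
    lab <- classify_bmi(bmi, runif(1, 3, 16), sample(c("boy", "girl"), 1), tab)
    codes <- as.integer(lab)
    expect_true(all(diff(codes) >= 0))          # never toward a lighter group
    expect_false(anyNA(lab))                    # every BMI gets a label
  }
  # interpolation: halfway between table ages sits halfway between cut-offs
  tab <- bmi_cutoff_table(data.frame(
    age_years = c(6, 10), sex = "boy",
    underweight_cutoff = c(13, 15), overweight_cutoff = c(17, 19),
    obese_cutoff = c(20, 24)))
  expect_equal(as.character(classify_bmi(c(13.99, 14.0), 8, "boy", tab)),
               c("underweight", "normal"))
  expect_equal(as.character(classify_bmi(c(21.99, 22.0), 8, "boy", tab)),
               c("overweight", "obese"))
})

test_that("the shipped cut-off table is internally valid", {
  tab <- default_bmi_cutoffs()
  expect_s3_class(tab, "bmi_cutoff_table")
  expect_true(all(tab$underweight_cutoff < tab$overweight_cutoff))
  expect_true(all(tab$overweight_cutoff < tab$obese_cutoff))
  expect_error(bmi_cutoff_table(data.frame(
    age_years = 8, sex = "boy", underweight_cutoff = 19,
    overweight_cutoff = 18, obese_cutoff = 21)), "increase")
})
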