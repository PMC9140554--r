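test_that("cohort generation is reproducible and validates its config", {
  cfg <- cohort_config(n_subjects = 120, rng_seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  d <- generate_cohort(cohort_config(n_subjects = 120, rng_seed = 8))
  expect_false(identical(a, d))

  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(group_weights = c(0.5, 0.5, 0.2, -0.2)),
               "group_weights")
  expect_error(cohort_config(group_weights = c(0.3, 0.3, 0.3, 0.2)),
               "group_weights")
  expect_error(cohort_config(mass_sd = c(1, 1, 0, 1)), "mass_sd")
  expect_error(cohort_config(prop_girls = 1.2), "prop_girls")
})

test_that("group counts match the calibration weights within sampling error", {
  co <- generate_cohort(table1_config(seed = 20))
  counts <- table(co$bmi_group)
  expected <- c(40, 431, 216, 128)
  # 4 binomial SDs per group
  sds <- sqrt(815 * (expected / 815) * (1 - expected / 815))
  expect_true(all(abs(as.numeric(counts) - expected) < 4 * sds))
  # sex split near 51% girls
  expect_equal(mean(co$sex == "girl"), 416 / 815, tolerance = 0.08)
})

test_that("degenerate group weights put everyone in one group", {
  cfg <- cohort_config(n_subjects = 50, group_weights = c(1, 0, 0, 0),
                       rng_seed = 3)
  co <- generate_cohort(cfg)
  expect_true(all(co$bmi_group == "underweight"))
})

test_that("generated measurements are physically admissible", {
  for (seed in c(1, 2, 3)) {
    co <- generate_cohort(cohort_config(n_subjects = 300, rng_seed = seed))
    expect_true(all(co$mass_kg > 0))
    expect_true(all(co$height_cm > 0))
    ft <- as.matrix(co[, c("ft1_s", "ft2_s", "ft3_s")])
    expect_true(all(ft > 0 & ft < 1.2))
    expect_true(all(co$age_years >= 6 & co$age_years < 12))
  }
})

test_that("BMI labels are consistent with generated mass and height", {
  co <- generate_cohort(table1_config(seed = 5))
  lab <- classify_bmi(compute_bmi(co$mass_kg, co$height_cm), co$age_years,
                      co$sex)
  expect_identical(as.character(lab), as.character(co$bmi_group))
})

test_that("group-mean CMJ falls and mass rises across BMI groups", {
  # the calibration's adjacent groups differ by as little as ~1 group-mean
  # standard error (underweight n = 40), so the pattern is asserted on the
  # expected group means, estimated by averaging 20 seeded cohorts
  acc <- matrix(0, 2L, 4L)
  for (seed in 1:20) {
    co <- generate_cohort(table1_config(seed = seed))
    m <- derive_metrics(co)
    acc[1L, ] <- acc[1L, ] + tapply(m$cmj_cm, m$bmi_group, mean)
    acc[2L, ] <- acc[2L, ] + tapply(m$mass_kg, m$bmi_group, mean)
  }
  expect_true(all(diff(acc[1L, ] / 20) < 0))   # CMJ non-increasing
  expect_true(all(diff(acc[2L, ] / 20) > 0))   # mass non-decreasing
})

test_that("best-of-three is meaningful and equals the drawn best height", {
  co <- generate_cohort(cohort_config(n_subjects = 200, rng_seed = 11))
  ft <- as.matrix(co[, c("ft1_s", "ft2_s", "ft3_s")])
  h <- flight_time_to_height(ft)
  # trials differ (jitter), but the best is shared by at least one trial
  expect_true(all(apply(h, 1L, function(x) length(unique(x)) > 1L)))
})

test_that("cohort CSV round-trips through the documented schema", {
  co <- generate_cohort(cohort_config(n_subjects = 30, rng_seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(names(back),
               c("id", "sex", "age_years", "height_cm", "mass_kg",
                 "ft1_s", "ft2_s", "ft3_s"))
  expect_equal(back$mass_kg, co$mass_kg, tolerance = 1e-9)
  expect_error(read_cohort(withr::local_tempfile(lines = "a,b\n1,2",
                                                 fileext = ".csv")),
               "missing column")
})

test_that("simulation from the generative model matches its mean structure", {
  X <- make_design(60, seed = 4)
  tp <- param_vector(alpha = 0.5, b_age = -0.2, b_pred = 0.7, sigma = 1e-12)
  y <- simulate_from_model(generative_config(tp, X, rng_seed = 1))
  mu <- tp[["alpha"]] + drop(X %*% tp[2:10])
  expect_equal(y, mu, tolerance = 1e-6)  # noiseless limit

  # repeated simulation: per-observation mean within 4 SE of mu
  tp2 <- param_vector(b_pred = 0.7, sigma = 0.8)
  Xs <- make_design(5, seed = 9)
  reps <- vapply(1:10000, function(i) {
    simulate_from_model(generative_config(tp2, Xs, rng_seed = 10000 + i))
  }, numeric(5L))
  mu2 <- tp2[["alpha"]] + drop(Xs %*% tp2[2:10])
  se <- 0.8 / sqrt(10000)
  expect_true(all(abs(rowMeans(reps) - mu2) < 4 * se))

  # fixed seed reproducibility
  cfg <- generative_config(tp2, Xs, rng_seed = 77)
  expect_identical(simulate_from_model(cfg), simulate_from_model(cfg))
})

test_that("an OLS fit on simulated data recovers the true slope", {
  # all terms at reference except the predictor column
  n <- 800
  set.seed(21)
  X <- matrix(0, n, 9L, dimnames = list(NULL, design_cols))
  X[, "predictor"] <- rnorm(n)
  tp <- param_vector(b_pred = 0.7, sigma = 0.6)
  y <- simulate_from_model(generative_config(tp, X, rng_seed = 31))
  fit <- lm(y ~ X[, "predictor"])
  est <- coef(summary(fit))[2L, ]
  expect_lt(abs(est[["Estimate"]] - 0.7), 3 * est[["Std. Error"]])

  # dimension mismatch is an error
  expect_error(generative_config(c(tp, 1), X), "11")
})
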