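# Shared fixtures, all generated in code.

design_cols <- c("age", "sex_girl", "bmi_normal", "bmi_overweight",
                 "bmi_obese", "predictor", "pred_x_normal",
                 "pred_x_overweight", "pred_x_obese")

# bare design matrix with every BMI group represented
make_design <- function(n, seed = 1) {
  set.seed(seed)
  grp <- c(1:4, sample.int(4L, n - 4L, replace = TRUE))
  X <- matrix(0, n, 9L, dimnames = list(NULL, design_cols))
  X[, "age"] <- stats::rnorm(n)
  X[, "sex_girl"] <- stats::rbinom(n, 1L, 0.5)
  X[, "bmi_normal"] <- as.numeric(grp == 2L)
  X[, "bmi_overweight"] <- as.numeric(grp == 3L)
  X[, "bmi_obese"] <- as.numeric(grp == 4L)
  X[, "predictor"] <- stats::rnorm(n)
  X[, 7:9] <- X[, "predictor"] * X[, 3:5]
  X
}

# small-but-converged sampler settings for unit tests
quick_fit <- function(design, outcome, seed = 1, ...) {
  sample_posterior(design, outcome, n_chains = 2L, n_iter = 1200L,
                   n_warmup = 400L, seed = seed, ...)
}

# hand-built posterior_draws object for deterministic evaluation tests
manual_draws <- function(mat, n_chains = 2L) {
  stopifnot(ncol(mat) == 11L, nrow(mat) %% n_chains == 0L)
  a <- array(NA_real_, dim = c(nrow(mat) / n_chains, n_chains, 11L),
             dimnames = list(NULL, paste0("chain", seq_len(n_chains)),
                             param_names()))
  for (ch in seq_len(n_chains)) {
    idx <- seq.int(ch, nrow(mat), by = n_chains)
    a[, ch, ] <- mat[idx, , drop = FALSE]
  }
  structure(list(draws = a, metadata = list(seed = NA, n_warmup = 0)),
            class = "posterior_draws")
}

# single-row toy cut-off table context (two ages so interpolation works)
toy_cutoffs <- function() {
  bmi_cutoff_table(data.frame(
    age_years = rep(c(2, 18), each = 2),
    sex = rep(c("boy", "girl"), 2),
    underweight_cutoff = 14.0,
    overweight_cutoff = 18.5,
    obese_cutoff = 21.5
  ))
}

table1_config <- function(seed = 1) cohort_config(rng_seed = seed)

small_cohort_metrics <- function(n = 200, seed = 1) {
  cfg <- cohort_config(n_subjects = n, rng_seed = seed)
  derive_metrics(generate_cohort(cfg))
}
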