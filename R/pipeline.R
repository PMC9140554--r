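model_definitions <- function() {
  list(
    model1 = list(outcome = "pp_duncan", predictor = "cmj_height"),
    model2 = list(outcome = "pp_duncan", predictor = "pe_cmj"),
    model3 = list(outcome = "pp_gomez", predictor = "cmj_height"),
    model4 = list(outcome = "pp_gomez", predictor = "pe_cmj")
  )
}

#' Fit one peak-power regression
#'
#' Builds the design matrix for the chosen predictor, z-scores the chosen
#' outcome, and samples the posterior. This is the unit the four-model
#' experiment repeats with each outcome/predictor pairing.
#'
#' @param metrics A [derive_metrics()] table.
#' @param outcome `"pp_duncan"` or `"pp_gomez"`.
#' @param predictor `"cmj_height"` or `"pe_cmj"`.
#' @param priors A [prior_spec()].
#' @param n_chains,n_iter,n_warmup,seed Passed to [sample_posterior()].
#' @param standardize_age Passed to [encode_design()].
#' @return List of class `power_model_fit`: `draws`, `design`, z-scored
#'   `outcome`, the outcome standardization params, and labels.
#' @export
fit_power_model <- function(metrics,
                            outcome = c("pp_duncan", "pp_gomez"),
                            predictor = c("cmj_height", "pe_cmj"),
                            priors = prior_spec(),
                            n_chains = 4L, n_iter = 3000L, n_warmup = 1000L,
                            seed = 1L, standardize_age = TRUE) {
  outcome <- match.arg(outcome)
  predictor <- match.arg(predictor)
  ycol <- switch(outcome, pp_duncan = "pp_duncan_W", pp_gomez = "pp_gomez_W")
  if (!(ycol %in% names(metrics))) {
    stop("metrics are missing the outcome column '", ycol, "'", call. = FALSE)
  }
  design <- encode_design(metrics, predictor, standardize_age)
  y_std <- zscore(metrics[[ycol]])
  draws <- sample_posterior(design, y_std$values, priors,
                            n_chains = n_chains, n_iter = n_iter,
                            n_warmup = n_warmup, seed = seed)
  structure(
    list(draws = draws, design = design, outcome = y_std$values,
         outcome_params = y_std$params, outcome_label = outcome,
         predictor_label = predictor),
    class = "power_model_fit"
  )
}

#' Evaluate a fitted model
#'
#' Bundles the comparison measures for one fit: Bayesian R-squared,
#' PSIS-LOO (ELPD/LOOIC), parameter posterior summaries, per-group
#' conditional slopes, and convergence diagnostics. Convergence problems
#' (R-hat >= 1.01 or ESS <= 1000, the study's convergence convention) are
#' returned as `warnings`.
#'
#' @param fit A [fit_power_model()] result.
#' @param level Credible level for all intervals.
#' @return List of class `evaluation_summary`.
#' @export
evaluate_fit <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "power_model_fit"))
  diag <- diagnostics(fit$draws)
  warnings <- character(0L)
  bad_rhat <- diag$parameter[!is.na(diag$rhat) & diag$rhat >= 1.01]
  if (length(bad_rhat) > 0L) {
    warnings <- c(warnings, paste0(
      "R-hat >= 1.01 for: ", paste(bad_rhat, collapse = ", "),
      " (convergence convention: R-hat = 1)"))
  }
  bad_ess <- diag$parameter[!is.na(diag$ess_bulk) & diag$ess_bulk <= 1000]
  if (length(bad_ess) > 0L) {
    warnings <- c(warnings, paste0(
      "bulk ESS <= 1000 for: ", paste(bad_ess, collapse = ", "),
      " (convergence convention: ESS > 1000)"))
  }
  ll <- pointwise_loglik(fit$draws, fit$design, fit$outcome)
  loo <- psis_loo(ll)
  if (any(loo$pareto_k > 0.7, na.rm = TRUE)) {
    warnings <- c(warnings, paste0(
      sum(loo$pareto_k > 0.7, na.rm = TRUE),
      " observation(s) with Pareto-k > 0.7; consider exact_loo()"))
  }
  structure(
    list(outcome = fit$outcome_label, predictor = fit$predictor_label,
         r2 = bayes_r2(fit$draws, fit$design, fit$outcome, level = level),
         loo = loo,
         parameters = parameter_summary(fit$draws, level),
         slopes = group_slopes(fit$draws, level),
         diagnostics = diag,
         warnings = warnings),
    class = "evaluation_summary"
  )
}

#' @export
print.evaluation_summary <- function(x, digits = 2, ...) {
  cat("model:", x$outcome, "~", x$predictor, "\n")
  cat(sprintf("  R2   %.2f (%.2f, %.2f)\n", x$r2$mean, x$r2$ci[1L],
              x$r2$ci[2L]))
  cat(sprintf("  elpd %.1f +/- %.1f   looic %.1f +/- %.1f\n",
              x$loo$elpd, x$loo$se, x$loo$looic, x$loo$looic_se))
  ps <- x$parameters
  for (i in seq_len(nrow(ps))) {
    cat(sprintf("  %-18s %6.2f (%6.2f, %6.2f)\n", ps$parameter[i],
                ps$mean[i], ps$lower[i], ps$upper[i]))
  }
  if (length(x$warnings) > 0L) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Run the four-model experiment end to end
#'
#' Derives metrics from a cohort (supplied or generated synthetically),
#' fits the four outcome/predictor pairings — peak power by the Duncan and
#' Gomez-Bruton equations, each predicted by CMJ height or by the
#' potential-energy index — evaluates each fit, and compares predictive
#' accuracy within each outcome with the potential-energy model in the
#' favoured position (positive ELPD difference = potential energy
#' predicts better).
#'
#' @param data Optional cohort data frame (see [read_cohort()] schema, or
#'   any [derive_metrics()]-compatible table). If `NULL`, a synthetic
#'   cohort is generated from `config`.
#' @param config A [cohort_config()] used when `data` is `NULL`.
#' @param cutoffs A [bmi_cutoff_table()].
#' @param equations Named list of [power_equation()]s with elements
#'   `duncan` and `gomez`.
#' @param priors A [prior_spec()].
#' @param n_chains,n_iter,n_warmup Sampler settings applied to every model.
#' @param seed Seed controlling every stochastic stage (per-model sampler
#'   seeds are derived from it).
#' @param g Gravitational acceleration in m/s^2.
#' @param standardize_age Passed to [encode_design()].
#' @param output_dir Optional directory; when given, the descriptive table,
#'   z-score trend, model summary table and comparisons are written as CSV.
#' @param verbose Log stage boundaries with row counts and timing.
#' @return List of class `run_report`: `metrics`, `describe`, `trend`,
#'   per-model `evaluations`, two `comparisons`, collected `warnings`, and
#'   provenance (seed, settings).
#' @export
run_experiment <- function(data = NULL,
                           config = cohort_config(),
                           cutoffs = default_bmi_cutoffs(),
                           equations = power_equations(),
                           priors = prior_spec(),
                           n_chains = 4L, n_iter = 3000L, n_warmup = 1000L,
                           seed = 1L, g = 9.79, standardize_age = TRUE,
                           output_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  if (is.null(data)) {
    config$rng_seed <- seed
    data <- generate_cohort(config, cutoffs, g)
    say("simulated cohort: %d subjects (seed %d)", nrow(data), seed)
  } else {
    say("input cohort: %d subjects", nrow(data))
  }
  metrics <- derive_metrics(data, cutoffs, equations, g)
  say("derived metrics: %d subjects classified", nrow(metrics))

  defs <- model_definitions()
  evaluations <- vector("list", 4L)
  names(evaluations) <- names(defs)
  fits <- vector("list", 4L)
  for (k in seq_along(defs)) {
    tm <- system.time({
      fits[[k]] <- fit_power_model(
        metrics, defs[[k]]$outcome, defs[[k]]$predictor, priors,
        n_chains = n_chains, n_iter = n_iter, n_warmup = n_warmup,
        seed = seed + k, standardize_age = standardize_age)
      evaluations[[k]] <- evaluate_fit(fits[[k]])
    })
    say("model %d (%s ~ %s): %.1fs", k, defs[[k]]$outcome,
        defs[[k]]$predictor, tm[["elapsed"]])
  }

  comparisons <- list(
    duncan = elpd_diff(evaluations$model2$loo, evaluations$model1$loo,
                       labels = c("model2 (pe_cmj)", "model1 (cmj_height)")),
    gomez = elpd_diff(evaluations$model4$loo, evaluations$model3$loo,
                      labels = c("model4 (pe_cmj)", "model3 (cmj_height)"))
  )

  all_warnings <- unlist(lapply(evaluations, `[[`, "warnings"))
  if (length(all_warnings) > 0L && verbose) {
    warning("convergence/diagnostic issues:\n  ",
            paste(all_warnings, collapse = "\n  "), call. = FALSE)
  }

  report <- structure(
    list(metrics = metrics,
         describe = describe_cohort(metrics),
         trend = zscore_trend(metrics),
         evaluations = evaluations,
         comparisons = comparisons,
         warnings = all_warnings,
         provenance = list(seed = seed, n_chains = n_chains, n_iter = n_iter,
                           n_warmup = n_warmup,
                           standardize_age = standardize_age,
                           prior_note = priors,
                           timestamp = format(t0))),
    class = "run_report"
  )
  if (!is.null(output_dir)) write_report(report, output_dir)
  say("experiment complete in %.1fs",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  report
}

#' Model-summary table of a run report
#'
#' One row per quantity (R2, LOOIC, ELPD, each parameter), one column per
#' model — the layout the comparison table of the source analysis uses.
#'
#' @param report A [run_experiment()] result.
#' @return Data frame of formatted summaries.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "run_report"))
  fmt_ci <- function(m, lo, hi) sprintf("%.2f (%.2f, %.2f)", m, lo, hi)
  fmt_se <- function(est, se) sprintf("%.1f +/- %.1f", est, se)
  cols <- lapply(report$evaluations, function(ev) {
    ps <- ev$parameters
    c(outcome = ev$outcome, predictor = ev$predictor,
      r2 = fmt_ci(ev$r2$mean, ev$r2$ci[1L], ev$r2$ci[2L]),
      looic = fmt_se(ev$loo$looic, ev$loo$looic_se),
      elpd = fmt_se(ev$loo$elpd, ev$loo$se),
      stats::setNames(fmt_ci(ps$mean, ps$lower, ps$upper), ps$parameter))
  })
  out <- data.frame(quantity = names(cols[[1L]]),
                    lapply(cols, unname),
                    row.names = NULL, check.names = FALSE)
  names(out) <- c("quantity", names(report$evaluations))
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("Four-model experiment (seed ", x$provenance$seed, ", n = ",
      nrow(x$metrics), ")\n\n", sep = "")
  print(report_table(x), right = FALSE)
  cat("\n")
  print(x$comparisons$duncan)
  print(x$comparisons$gomez)
  if (length(x$warnings) > 0L) {
    cat("\nwarnings:\n ", paste(x$warnings, collapse = "\n  "), "\n")
  }
  invisible(x)
}

write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$describe,
                   file.path(output_dir, "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(bmi_group = rownames(report$trend),
                              report$trend, row.names = NULL),
                   file.path(output_dir, "zscore_trend.csv"),
                   row.names = FALSE)
  utils::write.csv(report_table(report),
                   file.path(output_dir, "model_summaries.csv"),
                   row.names = FALSE)
  comp <- do.call(rbind, lapply(names(report$comparisons), function(nm) {
    cc <- report$comparisons[[nm]]
    data.frame(outcome = nm, favored = cc$favored, baseline = cc$baseline,
               elpd_diff = cc$elpd_diff, se = cc$se)
  }))
  utils::write.csv(comp, file.path(output_dir, "elpd_comparisons.csv"),
                   row.names = FALSE)
  slopes <- do.call(rbind, lapply(names(report$evaluations), function(nm) {
    data.frame(model = nm, report$evaluations[[nm]]$slopes$summary)
  }))
  utils::write.csv(slopes, file.path(output_dir, "group_slopes.csv"),
                   row.names = FALSE)
  invisible(output_dir)
}

#' Descriptive characteristics table
#'
#' Per-BMI-group and overall sample size, sex split, and mean +/- SD of
#' age, height, weight, BMI, CMJ height, the potential-energy index and
#' both peak-power estimates. SDs are `NA` for single-subject cells.
#'
#' @param metrics A [derive_metrics()] table.
#' @return Data frame, one row per variable, columns `all` plus the four
#'   groups.
#' @export
describe_cohort <- function(metrics) {
  stopifnot(nrow(metrics) >= 1L)
  grp <- factor(as.character(metrics$bmi_group), levels = bmi_groups())
  groups <- c(list(all = rep(TRUE, nrow(metrics))),
              stats::setNames(lapply(bmi_groups(), function(gp) grp == gp),
                              bmi_groups()))
  vars <- c(age_years = "age_years", height_cm = "height_cm",
            mass_kg = "mass_kg", bmi = "bmi", cmj_cm = "cmj_cm",
            pe_cmj = "pe_operational", pp_duncan_W = "pp_duncan_W",
            pp_gomez_W = "pp_gomez_W")
  rows <- list(
    data.frame(variable = "n",
               lapply(groups, function(idx) sum(idx)),
               check.names = FALSE),
    data.frame(variable = "pct_girls",
               lapply(groups, function(idx) {
                 if (sum(idx) == 0L) NA_real_
                 else 100 * mean(metrics$sex[idx] == "girl")
               }),
               check.names = FALSE)
  )
  for (v in names(vars)) {
    mrow <- data.frame(variable = paste0(v, "_mean"),
                       lapply(groups, function(idx) {
                         if (sum(idx) == 0L) NA_real_
                         else mean(metrics[[vars[[v]]]][idx])
                       }), check.names = FALSE)
    srow <- data.frame(variable = paste0(v, "_sd"),
                       lapply(groups, function(idx) {
                         if (sum(idx) < 2L) NA_real_
                         else stats::sd(metrics[[vars[[v]]]][idx])
                       }), check.names = FALSE)
    rows <- c(rows, list(mrow, srow))
  }
  out <- do.call(rbind, rows)
  names(out) <- c("variable", names(groups))
  out
}
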