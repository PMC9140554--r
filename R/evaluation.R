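#' Bayesian R-squared
#'
#' For each posterior draw \eqn{s}, computes the proportion of variance
#' explained for new data,
#' \deqn{R^2_s = \frac{V(\mu_s)}{V(\mu_s) + \sigma_s^2},}
#' where \eqn{V(\mu_s)} is the sample variance of the fitted values at that
#' draw. The default residual-variance term is the model-based draw of
#' \eqn{\sigma^2}, which matches the narrow credible intervals the method
#' produces on large samples; `method = "residual"` substitutes the
#' variance of the realized residuals at each draw.
#'
#' @param draws A `posterior_draws` object.
#' @param design A [encode_design()] object or bare n x 9 matrix.
#' @param outcome Outcome vector (needed only for `method = "residual"`).
#' @param method `"model"` (default) or `"residual"`.
#' @param level Credible level for the summary interval.
#' @return List of class `bayes_r2`: per-draw values (`draws`, all in
#'   \[0, 1\]), posterior `mean`, and central interval `ci`.
#' @export
bayes_r2 <- function(draws, design, outcome = NULL,
                     method = c("model", "residual"), level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(draws, "posterior_draws"))
  X <- as_design_matrix(design)
  m <- as.matrix(draws)
  if (nrow(m) == 0L) stop("draws are empty", call. = FALSE)
  mu <- cbind(1, X) %*% t(m[, 1:10, drop = FALSE])  # n x S
  var_fit <- apply(mu, 2L, stats::var)
  if (method == "model") {
    var_res <- m[, "sigma"]^2
  } else {
    if (is.null(outcome)) {
      stop("outcome is required for method = 'residual'", call. = FALSE)
    }
    var_res <- apply(outcome - mu, 2L, stats::var)
  }
  denom <- var_fit + var_res
  if (any(denom == 0)) {
    stop("R-squared undefined: zero fitted-value variance with sigma = 0",
         call. = FALSE)
  }
  r2 <- var_fit / denom
  a <- (1 - level) / 2
  structure(list(draws = r2, mean = mean(r2),
                 ci = stats::quantile(r2, c(a, 1 - a)), method = method),
            class = "bayes_r2")
}

#' Pointwise log-likelihood matrix
#'
#' Entry (s, i) is \eqn{\log N(y_i \mid \mu_i(\theta_s), \sigma_s)} — the
#' input PSIS-LOO needs.
#'
#' @inheritParams bayes_r2
#' @param outcome Outcome vector of length n.
#' @return S x n matrix (draws by observations).
#' @export
pointwise_loglik <- function(draws, design, outcome) {
  stopifnot(inherits(draws, "posterior_draws"))
  X <- as_design_matrix(design)
  if (nrow(X) != length(outcome)) {
    stop("design and outcome dimensions do not conform", call. = FALSE)
  }
  m <- as.matrix(draws)
  mu <- m[, 1:10, drop = FALSE] %*% t(cbind(1, X))  # S x n
  sigma <- m[, "sigma"]
  stats::dnorm(matrix(outcome, nrow = nrow(mu), ncol = ncol(mu), byrow = TRUE),
               mu, sigma, log = TRUE)
}

# Generalized-Pareto shape/scale fit to exceedances x > 0 by the
# Zhang--Stephens quantile/profile-posterior estimator, with the standard
# weak prior that regularizes the shape toward 1/2 for small tails.
gpd_fit <- function(x, wip = TRUE) {
  x <- sort(x)
  N <- length(x)
  M <- 30L + floor(sqrt(N))
  jj <- seq_len(M)
  xstar <- x[max(1L, floor(N / 4 + 0.5))]
  theta <- 1 / x[N] + (1 - sqrt(M / (jj - 0.5))) / (3 * xstar)
  prof <- vapply(theta, function(b) {
    k <- -mean(log1p(-b * x))
    N * (log(b / k) + k - 1)
  }, numeric(1L))
  w <- 1 / vapply(jj, function(j) sum(exp(prof - prof[j])), numeric(1L))
  b_hat <- sum(theta * w)
  # shape/scale in the (k, sigma) convention whose quantile function is
  # sigma * ((1-p)^(-k) - 1) / k; heavy tails give k > 0 (b_hat < 0)
  k_hat <- mean(log1p(-b_hat * x))
  sigma_hat <- -k_hat / b_hat
  if (wip) k_hat <- (k_hat * N + 5) / (N + 10)
  list(k = k_hat, sigma = sigma_hat)
}

# GPD quantile function (location 0) in the (k, sigma) parameterization
# used by gpd_fit
gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth one vector of log importance ratios; returns the smoothed
# (unnormalized) log weights and the fitted tail shape k
psis_smooth <- function(lr) {
  S <- length(lr)
  tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (tail_len < 5L) {
    return(list(log_weights = lr - max(lr), k = Inf))
  }
  ord <- order(lr)
  tail_idx <- ord[(S - tail_len + 1L):S]
  cutoff_lr <- lr[ord[S - tail_len]]
  max_lr <- lr[ord[S]]
  exceed <- exp(lr[tail_idx] - max_lr) - exp(cutoff_lr - max_lr)
  if (all(exceed <= 0) || stats::sd(exceed) == 0) {
    return(list(log_weights = lr - max_lr, k = -Inf))
  }
  fit <- gpd_fit(exceed)
  # replace tail weights by expected order statistics of the fitted GPD
  p <- (seq_len(tail_len) - 0.5) / tail_len
  smoothed <- log(gpd_quantile(p, fit$k, fit$sigma) +
                    exp(cutoff_lr - max_lr)) + max_lr
  lw <- lr
  lw[tail_idx[order(lr[tail_idx])]] <- smoothed
  lw <- pmin(lw, max_lr)  # truncate at the largest raw weight
  list(log_weights = lw - max_lr, k = fit$k)
}

#' PSIS-LOO cross-validation
#'
#' Approximates exact leave-one-out cross-validation from a single fit by
#' importance-weighting the posterior draws, with the largest importance
#' ratios for each observation stabilised by a generalized-Pareto fit to
#' the weight tail (tail size `min(0.2 S, 3 sqrt(S))`). Reports the
#' expected log pointwise predictive density (ELPD), its standard error,
#' the deviance-scale LOOIC = -2 ELPD, pointwise contributions, and the
#' Pareto-k tail-shape diagnostic per observation (k > 0.7 flags
#' observations whose importance weights are too heavy-tailed to trust;
#' they are reported, not refit — [exact_loo()] is the exact fallback).
#'
#' @param loglik S x n pointwise log-likelihood matrix (finite entries),
#'   typically from [pointwise_loglik()]; at least 100 draws recommended.
#' @return Object of class `loo_result` with elements `elpd`, `se`,
#'   `looic`, `looic_se`, `pointwise`, `pareto_k`, `n_obs`, `n_draws`.
#' @export
psis_loo <- function(loglik) {
  stopifnot(is.matrix(loglik))
  if (any(!is.finite(loglik))) {
    stop("non-finite values in the log-likelihood matrix", call. = FALSE)
  }
  S <- nrow(loglik)
  n <- ncol(loglik)
  if (S < 100L) {
    warning("fewer than 100 draws; PSIS-LOO estimates may be unstable")
  }
  pointwise <- numeric(n)
  k <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-loglik[, i])
    lw <- sm$log_weights - log_sum_exp(sm$log_weights)
    pointwise[i] <- log_sum_exp(lw + loglik[, i])
    k[i] <- sm$k
  }
  new_loo_result(pointwise, pareto_k = k, n_draws = S)
}

new_loo_result <- function(pointwise, pareto_k = rep(NA_real_,
                                                     length(pointwise)),
                           n_draws = NA_integer_) {
  elpd <- sum(pointwise)
  se <- sqrt(length(pointwise) * stats::var(pointwise))
  structure(
    list(elpd = elpd, se = se, looic = -2 * elpd, looic_se = 2 * se,
         pointwise = pointwise, pareto_k = pareto_k,
         n_obs = length(pointwise), n_draws = n_draws),
    class = "loo_result"
  )
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("elpd  %8.1f +/- %.1f\nlooic %8.1f +/- %.1f\n",
              x$elpd, x$se, x$looic, x$looic_se))
  if (any(is.finite(x$pareto_k))) {
    nk <- sum(x$pareto_k > 0.7, na.rm = TRUE)
    cat("Pareto-k > 0.7:", nk, "of", x$n_obs, "observations\n")
  }
  invisible(x)
}

#' LOOIC from an ELPD
#'
#' The leave-one-out information criterion is the ELPD on the deviance
#' scale: \eqn{LOOIC = -2\,ELPD}.
#'
#' @param x A `loo_result` or a numeric ELPD value.
#' @return Numeric LOOIC.
#' @export
looic <- function(x) {
  if (inherits(x, "loo_result")) return(x$looic)
  stopifnot(is.numeric(x))
  -2 * x
}

#' Exact leave-one-out cross-validation by refitting
#'
#' Refits the model n times, each time holding out one observation, and
#' scores it by the log posterior-mean predictive density of the held-out
#' point. Exact but n times the cost of a fit; used as the oracle for
#' [psis_loo()] on small problems and as the fallback for observations
#' with large Pareto-k.
#'
#' @inheritParams sample_posterior
#' @param ... Further arguments passed to [sample_posterior()].
#' @return A `loo_result` (Pareto-k entries are `NA`).
#' @export
exact_loo <- function(design, outcome, priors = prior_spec(), n_chains = 2L,
                      n_iter = 1500L, n_warmup = 500L, seed = 1L, ...) {
  X <- as_design_matrix(design)
  n <- length(outcome)
  pointwise <- numeric(n)
  for (i in seq_len(n)) {
    fit <- sample_posterior(X[-i, , drop = FALSE], outcome[-i], priors,
                            n_chains = n_chains, n_iter = n_iter,
                            n_warmup = n_warmup, seed = seed + i, ...)
    m <- as.matrix(fit)
    mu_i <- drop(m[, 1:10, drop = FALSE] %*% c(1, X[i, ]))
    ll_i <- stats::dnorm(outcome[i], mu_i, m[, "sigma"], log = TRUE)
    pointwise[i] <- log_sum_exp(ll_i) - log(length(ll_i))
  }
  new_loo_result(pointwise)
}

#' PSIS-LOO with exact refits for flagged observations
#'
#' Runs [psis_loo()] and then replaces the pointwise ELPD of every
#' observation whose Pareto-k exceeds `k_threshold` with the exact
#' refit-without-that-observation value — the standard fallback when the
#' importance weights are too heavy-tailed to trust, which happens
#' routinely when the number of observations is small relative to the 11
#' model parameters (leave-one-out then perturbs the posterior too much
#' for importance sampling). Costs one refit per flagged observation.
#'
#' @param draws A `posterior_draws` object for the full-data fit.
#' @inheritParams exact_loo
#' @param k_threshold Pareto-k above which an observation is refit
#'   exactly (default 0.7).
#' @param ... Passed to [sample_posterior()] for the refits.
#' @return A `loo_result`; refit observations keep their k value but their
#'   contribution is exact.
#' @export
psis_loo_refit <- function(draws, design, outcome, priors = prior_spec(),
                           k_threshold = 0.7, n_chains = 2L, n_iter = 1500L,
                           n_warmup = 500L, seed = 1L, ...) {
  X <- as_design_matrix(design)
  ps <- psis_loo(pointwise_loglik(draws, X, outcome))
  flagged <- which(ps$pareto_k > k_threshold)
  for (i in flagged) {
    fit <- sample_posterior(X[-i, , drop = FALSE], outcome[-i], priors,
                            n_chains = n_chains, n_iter = n_iter,
                            n_warmup = n_warmup, seed = seed + i, ...)
    m <- as.matrix(fit)
    mu_i <- drop(m[, 1:10, drop = FALSE] %*% c(1, X[i, ]))
    ll_i <- stats::dnorm(outcome[i], mu_i, m[, "sigma"], log = TRUE)
    ps$pointwise[i] <- log_sum_exp(ll_i) - log(length(ll_i))
  }
  out <- new_loo_result(ps$pointwise, pareto_k = ps$pareto_k,
                        n_draws = ps$n_draws)
  out$n_refit <- length(flagged)
  out
}

#' ELPD difference between two models
#'
#' Computes `elpd(favored) - elpd(baseline)` with the paired standard
#' error from the pointwise ELPD differences (the cited method's
#' convention; pooling the two SEs would ignore the strong correlation of
#' pointwise contributions on shared data). A positive value favours the
#' first argument. In the source analysis the favoured position is the
#' model with the potential-energy predictor. Numeric scalars are accepted
#' for desk arithmetic on printed ELPDs (the SE is then `NA`).
#'
#' @param favored,baseline `loo_result` objects on the same observations,
#'   or numeric ELPD scalars.
#' @param labels Optional character pair naming the two models.
#' @return List of class `elpd_comparison`: `elpd_diff`, `se`, labels.
#' @export
elpd_diff <- function(favored, baseline, labels = c("favored", "baseline")) {
  if (is.numeric(favored) && is.numeric(baseline)) {
    return(structure(list(elpd_diff = favored - baseline, se = NA_real_,
                          favored = labels[1L], baseline = labels[2L]),
                     class = "elpd_comparison"))
  }
  stopifnot(inherits(favored, "loo_result"), inherits(baseline, "loo_result"))
  if (favored$n_obs != baseline$n_obs) {
    stop("models were evaluated on different numbers of observations",
         call. = FALSE)
  }
  d <- favored$pointwise - baseline$pointwise
  structure(
    list(elpd_diff = sum(d), se = sqrt(length(d) * stats::var(d)),
         favored = labels[1L], baseline = labels[2L]),
    class = "elpd_comparison"
  )
}

#' @export
print.elpd_comparison <- function(x, ...) {
  cat(sprintf("elpd_diff (%s - %s) = %.1f", x$favored, x$baseline,
              x$elpd_diff))
  if (is.finite(x$se)) cat(sprintf(" +/- %.1f", x$se))
  cat("\n  positive favours", x$favored, "\n")
  invisible(x)
}

#' Per-BMI-group conditional predictor slopes
#'
#' With underweight as the reference level, the predictor coefficient is
#' the underweight slope and each interaction coefficient is that group's
#' deviation, so group g's conditional slope per draw is
#' `b_pred + b_pred_<g>` (and exactly `b_pred` for underweight).
#'
#' @param draws A `posterior_draws` object.
#' @param level Credible level.
#' @return List of class `group_slopes`: `summary` data frame (group,
#'   mean, lower, upper) and the per-draw slope matrix `draws`.
#' @export
group_slopes <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  m <- as.matrix(draws)
  slopes <- cbind(
    underweight = m[, "b_pred"],
    normal = m[, "b_pred"] + m[, "b_pred_normal"],
    overweight = m[, "b_pred"] + m[, "b_pred_overweight"],
    obese = m[, "b_pred"] + m[, "b_pred_obese"]
  )
  a <- (1 - level) / 2
  structure(
    list(summary = data.frame(
           group = factor(bmi_groups(), levels = bmi_groups()),
           mean = colMeans(slopes),
           lower = apply(slopes, 2L, stats::quantile, probs = a),
           upper = apply(slopes, 2L, stats::quantile, probs = 1 - a),
           row.names = NULL),
         draws = slopes),
    class = "group_slopes"
  )
}

#' Per-BMI-group means of whole-sample z-scores
#'
#' Standardizes CMJ height, the potential-energy index, and both peak-power
#' estimates over the whole sample, then averages the z-scores within each
#' BMI group — the descriptive trend display contrasting how raw jump
#' height and the mass-aware indices move across weight-status groups.
#'
#' @param metrics A [derive_metrics()] table.
#' @return 4 x 4 numeric matrix, groups (rows) by variables
#'   (cmj, pe_cmj, pp_duncan, pp_gomez); `NA` (with a message) for an
#'   empty group.
#' @export
zscore_trend <- function(metrics) {
  vars <- c(cmj = "cmj_cm", pe_cmj = "pe_operational",
            pp_duncan = "pp_duncan_W", pp_gomez = "pp_gomez_W")
  missing_cols <- setdiff(unname(vars), names(metrics))
  if (length(missing_cols) > 0L) {
    stop("metrics are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  grp <- factor(as.character(metrics$bmi_group), levels = bmi_groups())
  out <- matrix(NA_real_, nrow = 4L, ncol = length(vars),
                dimnames = list(bmi_groups(), names(vars)))
  for (v in names(vars)) {
    z <- zscore(metrics[[vars[[v]]]])$values
    means <- tapply(z, grp, mean)
    out[, v] <- as.numeric(means)
  }
  if (any(is.na(out))) {
    message("empty BMI group(s): ",
            paste(rownames(out)[apply(out, 1L, anyNA)], collapse = ", "))
  }
  out
}
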