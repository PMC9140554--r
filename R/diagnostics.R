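# --- convergence diagnostics -------------------------------------------
# Rank-normalized split R-hat and bulk effective sample size, the modern
# forms of the between/within-chain variance diagnostic: chains are split
# in half, all draws are replaced by their normal scores (ranks mapped
# through the standard-normal quantile function), and the classic
# potential-scale-reduction / autocorrelation machinery is applied to the
# transformed draws.

# n x m matrix -> (n/2) x 2m matrix (one draw dropped if n is odd)
split_chains <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  cbind(x[seq_len(half), , drop = FALSE],
        x[(n - half + 1):n, , drop = FALSE])
}

# normal scores of the pooled draws (average ranks for ties)
rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  matrix(z, nrow = nrow(x), ncol = ncol(x))
}

# classic split-free R-hat on an n x m matrix of draws
rhat_basic <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  chain_means <- colMeans(x)
  W <- mean(apply(x, 2L, stats::var))
  B <- n * stats::var(chain_means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split R-hat
#'
#' @param x Matrix of draws, iterations x chains (>= 2 chains), or a
#'   `posterior_draws` object (then one value per parameter).
#' @return R-hat value(s); near 1 indicates the chains agree.
#' @export
rhat <- function(x) {
  if (inherits(x, "posterior_draws")) {
    return(apply(x$draws, 3L, function(p) rhat(as.matrix(p))))
  }
  stopifnot(is.matrix(x))
  if (ncol(x) < 2L) stop("R-hat requires at least 2 chains", call. = FALSE)
  if (stats::var(as.vector(x)) == 0) return(NA_real_)
  rhat_basic(rank_normalize(split_chains(x)))
}

# autocovariance sequence (biased, divides by n) of one chain
autocov <- function(x) {
  n <- length(x)
  a <- stats::acf(x, lag.max = n - 1L, type = "covariance", plot = FALSE,
                  demean = TRUE)$acf[, 1L, 1L]
  a * (n - 1) / n
}

# effective sample size of an n x m draw matrix via the combined-chain
# autocorrelation with Geyer's initial monotone positive sequence
ess_basic <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4L) stop("ESS requires at least 4 draws per chain", call. = FALSE)
  acov <- apply(x, 2L, autocov)
  chain_means <- colMeans(x)
  mean_var <- mean(acov[1L, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1L) var_plus <- var_plus + stats::var(chain_means)
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)

  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus  # rho[t+1] = lag t
  rho[1L] <- 1
  # Geyer: sum adjacent-lag pairs while positive, then force the pair
  # sums to be non-increasing (initial monotone positive sequence)
  max_pairs <- floor((length(rho) - 1L) / 2)
  pair_sums <- numeric(0L)
  for (k in seq_len(max_pairs)) {
    p <- rho[2L * k - 1L] + rho[2L * k]
    if (k > 1L && (!is.finite(p) || p < 0)) break
    pair_sums <- c(pair_sums, p)
  }
  pair_sums <- cummin(pair_sums)
  tau <- max(-1 + 2 * sum(pair_sums), 1 / log10(n * m + 10))
  min(n * m / tau, n * m * log10(n * m))
}

#' Bulk effective sample size
#'
#' ESS of the rank-normalized split chains — the number of independent
#' draws the correlated sample is worth for estimating central quantities.
#'
#' @inheritParams rhat
#' @return ESS value(s).
#' @export
ess_bulk <- function(x) {
  if (inherits(x, "posterior_draws")) {
    return(apply(x$draws, 3L, function(p) ess_bulk(as.matrix(p))))
  }
  stopifnot(is.matrix(x))
  if (stats::var(as.vector(x)) == 0) return(NA_real_)
  ess_basic(rank_normalize(split_chains(x)))
}

#' Convergence diagnostics for posterior draws
#'
#' Computes rank-normalized split R-hat and bulk ESS for every parameter.
#' The study's convergence convention is R-hat of 1 (in practice < 1.01)
#' and ESS above 1000.
#'
#' @param draws A `posterior_draws` object with >= 2 chains and >= 4 draws
#'   per chain.
#' @return Data frame with columns `parameter`, `rhat`, `ess_bulk`.
#' @export
diagnostics <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  d <- dim(draws$draws)
  if (d[2L] < 2L) {
    stop("diagnostics require at least 2 chains (R-hat is undefined ",
         "for a single chain under the split-rank method)", call. = FALSE)
  }
  if (d[1L] < 4L) stop("diagnostics require at least 4 draws per chain",
                       call. = FALSE)
  data.frame(
    parameter = dimnames(draws$draws)[[3L]],
    rhat = rhat(draws),
    ess_bulk = ess_bulk(draws),
    row.names = NULL
  )
}
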