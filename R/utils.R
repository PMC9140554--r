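`%||%` <- function(x, y) if (is.null(x)) y else x

# numerically stable log(sum(exp(x)))
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# normal draws truncated to (0, Inf) by rejection; mean/sd vectorised
rtruncnorm_pos <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= 0]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncated-normal rejection failed to converge",
                             call. = FALSE)
  }
  x
}

# location-scale Student-t log density
dstudent_t_log <- function(x, df, location, scale) {
  stats::dt((x - location) / scale, df = df, log = TRUE) - log(scale)
}

# half-Student-t (support x >= 0) log density
dhalf_student_t_log <- function(x, df, location, scale) {
  ifelse(x < 0, -Inf, log(2) + dstudent_t_log(x, df, location, scale))
}
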