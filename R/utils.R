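# Internal helpers shared across modules.

# Multiplicative lognormal noise with unit mean and coefficient of variation
# `cv`; cytometry intensities are positive and right-skewed, so all generator
# noise in the package is of this family.
lnorm_mult <- function(n, cv) {
  if (cv < 0) stopf("noise CV must be >= 0, got %g", cv)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0)
    stopf("'%s' must be > 0, got %g", name, x)
  invisible(x)
}

# Quantile-bin assignment with the package-wide tie rule: values equal to an
# edge go to the lower bin.  `edges` are the k-1 interior cut points.
assign_bins <- function(x, edges) {
  findInterval(x, edges, left.open = TRUE) + 1L
}

# Piecewise-linear time profile from breakpoints, constant beyond the ends.
profile_fun <- function(breaks, default) {
  if (is.null(breaks) || nrow(breaks) == 0L)
    return(function(t) rep(default, length(t)))
  if (nrow(breaks) == 1L) {
    v <- breaks[[2L]][1L]
    return(function(t) rep(v, length(t)))
  }
  stats::approxfun(breaks[[1L]], breaks[[2L]], rule = 2)
}
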