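#' Single-pass mean +/- k SD outlier filter
#'
#' Removes events lying more than \code{k} standard deviations from the mean,
#' the standard cleanup applied to each bead group and to per-population
#' cytometry feature distributions.  The mean and SD are computed once on the
#' full input (no re-estimation after removal); with \code{log_scale = TRUE}
#' the filter operates on log-transformed values, matching log-normalized
#' population distributions.
#'
#' @param values Numeric vector, non-empty; strictly positive if
#'   \code{log_scale}.
#' @param k SD multiple (default 3).
#' @param log_scale Filter on the log scale.
#' @return List with \code{keep} (logical vector), \code{removed_fraction},
#'   and \code{bounds} (on the original scale).
#' @examples
#' filter_outliers(c(rnorm(100), 50))$removed_fraction
#' @export
filter_outliers <- function(values, k = 3, log_scale = FALSE) {
  if (length(values) == 0L) stopf("'values' must be non-empty")
  if (!all(is.finite(values))) stopf("'values' must be finite")
  check_scalar_num(k, "k")
  if (k < 0) stopf("'k' must be >= 0")
  x <- values
  if (log_scale) {
    if (any(values <= 0)) stopf("log-scale filtering requires positive values")
    x <- log(values)
  }
  s <- stats::sd(x)
  if (s == 0 || is.na(s)) {
    if (k == 0)
      stopf("all values identical and k = 0: filter undefined")
    return(list(keep = rep(TRUE, length(values)), removed_fraction = 0,
                bounds = range(values)))
  }
  m <- mean(x)
  keep <- x >= m - k * s & x <= m + k * s
  if (!any(keep)) stopf("filter would remove every event; refusing")
  bounds <- c(m - k * s, m + k * s)
  if (log_scale) bounds <- exp(bounds)
  list(keep = keep, removed_fraction = mean(!keep), bounds = bounds)
}

#' Fit a bead size calibration
#'
#' Fits the degree-2 polynomial \eqn{A(d) = c_0 + c_1 d + c_2 d^2} of measured
#' event area (px^2) on manufacturer bead diameter (um), after removing, within
#' each bead group, events more than \code{k} SD from the group mean.  The
#' calibration is the instrument's size standard: it converts measured areas
#' to physical diameters via [area_to_diameter()].
#'
#' The fit must be strictly increasing over its domain (the bead diameter
#' range extended by 10% of its span on each side) with positive curvature;
#' otherwise an error names the offending interval.
#'
#' @param events Data frame with columns \code{area} and \code{true_diameter}
#'   (or \code{bead_id} plus the \code{diameters} argument).
#' @param diameters Optional vector of manufacturer diameters to use (subsets
#'   the table).
#' @param k Per-group outlier-filter SD multiple.
#' @return An object of class \code{"bead_calibration"}: coefficients
#'   \code{c0, c1, c2}, \code{r2}, monotone \code{domain} (um), area range
#'   \code{area_range} (px^2 over the domain), and \code{removed_fraction}.
#' @export
fit_bead_calibration <- function(events, diameters = NULL, k = 3) {
  if (!all(c("area") %in% names(events)))
    stopf("'events' must have an 'area' column")
  if (!"true_diameter" %in% names(events))
    stopf("'events' must have a 'true_diameter' column of manufacturer sizes")
  if (!is.null(diameters))
    events <- events[events$true_diameter %in% diameters, , drop = FALSE]
  ds <- sort(unique(events$true_diameter))
  if (length(ds) < 3L)
    stopf("need >= 3 distinct bead diameters, got %d", length(ds))
  kept <- vector("list", length(ds))
  removed <- 0L
  for (i in seq_along(ds)) {
    g <- events[events$true_diameter == ds[i], , drop = FALSE]
    if (nrow(g) < 10L)
      stopf("bead group d = %g um has fewer than 10 events", ds[i])
    f <- filter_outliers(g$area, k = k)
    removed <- removed + sum(!f$keep)
    kept[[i]] <- g[f$keep, , drop = FALSE]
  }
  dat <- do.call(rbind, kept)
  fit <- stats::lm(area ~ true_diameter + I(true_diameter^2), data = dat)
  cf <- unname(stats::coef(fit))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  span <- diff(range(ds))
  domain <- c(max(min(ds) - 0.1 * span, 0), max(ds) + 0.1 * span)
  # strictly increasing iff A'(d) = c1 + 2 c2 d > 0 on the domain
  dgrid <- c(domain[1], domain[2])
  slope_ends <- cf[2] + 2 * cf[3] * dgrid
  if (cf[3] <= 0)
    stopf("calibration curvature c2 = %g is not positive", cf[3])
  if (any(slope_ends <= 0))
    stopf("calibration is non-monotone on [%.3g, %.3g] um",
          domain[1], -cf[2] / (2 * cf[3]))
  forward <- function(d) cf[1] + cf[2] * d + cf[3] * d^2
  structure(list(c0 = cf[1], c1 = cf[2], c2 = cf[3], r2 = r2,
                 domain = domain, area_range = forward(domain),
                 removed_fraction = removed / nrow(events),
                 n_events = nrow(dat)),
            class = "bead_calibration")
}

#' @export
print.bead_calibration <- function(x, ...) {
  cat("Bead size calibration: area = c0 + c1*d + c2*d^2\n")
  cat(sprintf("  c0 = %.4g, c1 = %.4g, c2 = %.4g (px^2 per um powers)\n",
              x$c0, x$c1, x$c2))
  cat(sprintf("  R^2 = %.4f on %d events (%.2f%% removed by 3-SD filter)\n",
              x$r2, x$n_events, 100 * x$removed_fraction))
  cat(sprintf("  monotone domain: %.2f - %.2f um\n", x$domain[1], x$domain[2]))
  invisible(x)
}

#' Forward calibration: diameter to expected area
#'
#' @param cal A [fit_bead_calibration()] result.
#' @param diameters Diameters, um.
#' @return Expected areas, px^2.
#' @export
bead_area <- function(cal, diameters) {
  stopifnot(inherits(cal, "bead_calibration"))
  cal$c0 + cal$c1 * diameters + cal$c2 * diameters^2
}

#' Invert a bead calibration: area to diameter
#'
#' Solves \eqn{c_2 d^2 + c_1 d + (c_0 - A) = 0} on the increasing branch,
#' \eqn{d = (-c_1 + \sqrt{c_1^2 - 4 c_2 (c_0 - A)}) / (2 c_2)}.  Areas outside
#' the calibrated area range are still inverted but flagged as extrapolation
#' with a warning (attribute \code{"extrapolated"}).
#'
#' @param cal A [fit_bead_calibration()] result.
#' @param areas Measured areas, px^2.
#' @return Diameters in um, with a logical attribute \code{"extrapolated"}.
#' @export
area_to_diameter <- function(cal, areas) {
  stopifnot(inherits(cal, "bead_calibration"))
  disc <- cal$c1^2 - 4 * cal$c2 * (cal$c0 - areas)
  if (any(disc < 0))
    stopf("negative discriminant for %d area value(s): below the curve minimum",
          sum(disc < 0))
  d <- (-cal$c1 + sqrt(disc)) / (2 * cal$c2)
  extrap <- areas < min(cal$area_range) | areas > max(cal$area_range)
  if (any(extrap))
    warnf("%d area value(s) outside the calibrated range [%.3g, %.3g] px^2: extrapolating",
          sum(extrap), min(cal$area_range), max(cal$area_range))
  attr(d, "extrapolated") <- extrap
  d
}
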