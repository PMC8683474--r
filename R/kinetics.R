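#' Fit exponential growth and doubling time
#'
#' Ordinary least squares of log2 counts on time: the slope is the growth
#' rate in doublings per hour and its reciprocal the doubling time.  The 95%
#' confidence interval comes from the slope's standard error and t quantile,
#' transformed to the doubling-time scale (interval endpoints are the
#' reciprocals of the slope bounds).  R^2 is reported on the log scale.
#'
#' A non-positive fitted slope yields an infinite doubling time with a
#' warning (a flat or shrinking culture has no doubling time).
#'
#' @param times Sampling times, hours (>= 3 distinct values).
#' @param counts Positive cell counts.
#' @param level Confidence level (default 0.95).
#' @return Object of class \code{"growth_fit"}: \code{rate_log2} (1/h),
#'   \code{rate_ln} (1/h), \code{doubling_time} (h), \code{ci95} (h),
#'   \code{r2}, \code{n_points}.
#' @export
fit_exponential_growth <- function(times, counts, level = 0.95) {
  if (length(times) != length(counts)) stopf("lengths differ")
  if (length(times) < 3L) stopf("need >= 3 timepoints")
  if (any(counts <= 0)) stopf("counts must be positive")
  if (stats::sd(times) == 0) stopf("times must vary")
  fit <- stats::lm(log2(counts) ~ times)
  slope <- unname(stats::coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  ci_slope <- suppressWarnings(stats::confint(fit, "times", level = level))
  lo_s <- ci_slope[1]; hi_s <- ci_slope[2]
  if (slope <= 0) {
    warnf("non-positive growth slope (%.3g): doubling time infinite", slope)
    dt <- Inf
    ci <- c(if (hi_s > 0) 1 / hi_s else Inf, Inf)
  } else {
    dt <- 1 / slope
    ci <- c(1 / hi_s, if (lo_s > 0) 1 / lo_s else Inf)
  }
  structure(list(rate_log2 = slope, rate_ln = slope * log(2),
                 doubling_time = dt, ci95 = ci, r2 = r2,
                 n_points = length(times)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Exponential growth fit (n = %d): doubling time %.3g h (95%% CI %.3g - %.3g), R^2 = %.3f\n",
              x$n_points, x$doubling_time, x$ci95[1], x$ci95[2], x$r2))
  invisible(x)
}

# kernel-density peaks, tallest first, greedily enforcing a minimum
# separation of min_sep_factor * bandwidth between accepted peaks
find_density_peaks <- function(x, min_sep_factor = 1.5, min_height_frac = 0.1) {
  d <- stats::density(x)
  y <- d$y
  is_max <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                     y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  is_max <- is_max & y >= min_height_frac * max(y)   # drop tail ripples
  locs <- d$x[is_max]
  hts <- y[is_max]
  ord <- order(-hts, locs)   # ties broken toward the lower mode
  kept <- numeric(0)
  min_sep <- min_sep_factor * d$bw
  for (i in ord) {
    if (all(abs(locs[i] - kept) >= min_sep)) kept <- c(kept, locs[i])
  }
  sort(kept)
}

#' BrdU/DNA cell-cycle gating
#'
#' Classifies events from a BrdU-pulse experiment into G1, S and G2/M.
#' S-phase events are BrdU-positive, split from background at a threshold
#' that is either supplied (negative control) or found as the valley between
#' the two modes of log BrdU intensity.  BrdU-negative events are split into
#' G1 (near-2N) and G2/M (near-4N) at the midpoint of the 2N and 4N DNA mode
#' centers, located by kernel-density peak detection; if only the 2N mode is
#' detectable, 4N is taken as twice its position.
#'
#' The intra-S-phase BrdU intensity (\code{s_mfi}) measures the DNA synthesis
#' rate, which is inversely related to S-phase duration.
#'
#' @param dna DNA content values (a.u.).
#' @param brdu BrdU intensities (a.u., positive).
#' @param brdu_threshold Optional BrdU positivity threshold (a.u.).
#' @param min_events Minimum events (default 200).
#' @param mfi_stat \code{"median"} (default) or \code{"mean"}.
#' @return Object of class \code{"cellcycle_stats"}: \code{f_g1, f_s, f_g2m}
#'   (sum to 1), \code{s_gate} (description list), \code{s_mfi},
#'   \code{phase} (per-event factor).
#' @export
cellcycle_gate <- function(dna, brdu, brdu_threshold = NULL,
                           min_events = 200L, mfi_stat = c("median", "mean")) {
  mfi_stat <- match.arg(mfi_stat)
  n <- length(dna)
  if (length(brdu) != n) stopf("lengths differ")
  if (n < min_events) stopf("need >= %d events, got %d", min_events, n)
  if (any(brdu <= 0)) stopf("BrdU intensities must be positive")
  lb <- log(brdu)
  if (is.null(brdu_threshold)) {
    pk <- find_density_peaks(lb)
    if (length(pk) >= 2L) {
      # valley: minimum of the density between the two dominant modes
      d <- stats::density(lb)
      lo <- pk[1]; hi <- pk[length(pk)]
      mid <- d$x > lo & d$x < hi
      log_thr <- d$x[mid][which.min(d$y[mid])]
    } else {
      # single mode (e.g. no S phase): positives must clear the mode by a
      # wide margin
      log_thr <- pk[1] + 4 * stats::mad(lb)
    }
    brdu_threshold <- exp(log_thr)
  }
  s <- brdu > brdu_threshold
  if (sum(!s) < 10L) stopf("no BrdU-negative events: cannot anchor DNA peaks")
  pk_dna <- find_density_peaks(dna[!s])
  if (length(pk_dna) == 0L) stopf("no detectable 2N peak")
  p2n <- pk_dna[1]
  if (p2n <= 0) stopf("no detectable 2N peak")
  upper <- pk_dna[pk_dna > 1.5 * p2n]
  p4n <- if (length(upper)) upper[1] else 2 * p2n
  boundary <- (p2n + p4n) / 2
  phase <- ifelse(s, "s", ifelse(dna < boundary, "g1", "g2m"))
  phase <- factor(phase, levels = c("g1", "s", "g2m"))
  f <- as.numeric(table(phase)) / n
  s_mfi <- if (any(s)) {
    if (mfi_stat == "median") stats::median(brdu[s]) else mean(brdu[s])
  } else NA_real_
  structure(list(f_g1 = f[1], f_s = f[2], f_g2m = f[3],
                 s_gate = list(brdu_threshold = brdu_threshold,
                               dna_2n = p2n, dna_4n = p4n,
                               g1_g2m_boundary = boundary,
                               mfi_stat = mfi_stat),
                 s_mfi = s_mfi, phase = phase),
            class = "cellcycle_stats")
}

#' @export
print.cellcycle_stats <- function(x, ...) {
  cat(sprintf("Cell-cycle fractions: G1 %.1f%%, S %.1f%%, G2/M %.1f%%\n",
              100 * x$f_g1, 100 * x$f_s, 100 * x$f_g2m))
  cat(sprintf("  S-phase BrdU %s = %.4g (threshold %.4g a.u.)\n",
              x$s_gate$mfi_stat, x$s_mfi, x$s_gate$brdu_threshold))
  invisible(x)
}

#' Intra-S-phase speed ratio
#'
#' Ratio of the S-gate BrdU intensity statistic to a reference value (e.g.
#' the survival-only arm at t = 0), expressing the intra-S-phase DNA
#' synthesis rate relative to that reference.
#'
#' @param stats A [cellcycle_gate()] result.
#' @param reference_mfi Positive reference BrdU MFI.
#' @return The speed ratio (unitless).
#' @export
s_phase_speed <- function(stats, reference_mfi) {
  stopifnot(inherits(stats, "cellcycle_stats"))
  check_scalar_num(reference_mfi, "reference_mfi", positive = TRUE)
  if (!is.finite(stats$s_mfi)) stopf("empty S gate: no S-phase MFI")
  stats$s_mfi / reference_mfi
}

#' Summarize fluorescent-timer blue/total ratios
#'
#' Per-cell ratio \eqn{B/(B+R)} of blue to total timer fluorescence; higher
#' values indicate faster cycling.  Events with zero total are dropped and
#' counted.
#'
#' @param blue,red Paired nonnegative channel intensities (n >= 100).
#' @return Object of class \code{"ft_summary"}: \code{ratio} (per cell),
#'   \code{median_ratio}, \code{mean_ratio}, \code{quartiles}, \code{n},
#'   \code{n_dropped}.
#' @export
ft_ratio_summary <- function(blue, red) {
  n <- length(blue)
  if (length(red) != n) stopf("channels must be paired")
  if (n < 100L) stopf("need >= 100 cells, got %d", n)
  if (any(blue < 0) || any(red < 0)) stopf("intensities must be nonnegative")
  total <- blue + red
  keep <- total > 0
  if (!any(keep)) stopf("all totals are zero")
  ratio <- blue[keep] / total[keep]
  structure(list(ratio = ratio, median_ratio = stats::median(ratio),
                 mean_ratio = mean(ratio),
                 quartiles = stats::quantile(ratio, c(0.25, 0.5, 0.75),
                                             names = FALSE),
                 n = sum(keep), n_dropped = sum(!keep)),
            class = "ft_summary")
}

#' @export
print.ft_summary <- function(x, ...) {
  cat(sprintf("Timer B/(B+R): median %.4f (IQR %.4f - %.4f), n = %d (%d dropped)\n",
              x$median_ratio, x$quartiles[1], x$quartiles[3], x$n, x$n_dropped))
  invisible(x)
}

# model-implied median B/(B+R) at cycle length T and maturation time tau:
# median over the steady-state age density of min(a, tau) / (T + a)
ft_median_model <- function(T, tau, m = 4001L) {
  u <- (seq_len(m) - 0.5) / m
  a <- ft_age_quantile(u, T)
  stats::median(pmin(a, tau) / (T + a))
}

#' Relative cell-cycle length from timer summaries
#'
#' Converts two [ft_ratio_summary()] results into a ratio of cell-cycle
#' lengths, sample over reference.  The default \code{"quadrature"} model
#' numerically inverts the steady-state mapping from cycle length T to the
#' median \eqn{B/(B+R)} at the given maturation time tau (a strictly
#' decreasing mapping, enforced); \code{"reciprocal"} uses the first-order
#' shortcut that the median ratio is inversely proportional to T, i.e.
#' reference median / sample median.
#'
#' @param sample,reference [ft_ratio_summary()] objects from populations with
#'   comparable tau.
#' @param tau Timer maturation time, hours.
#' @param model \code{"quadrature"} (default) or \code{"reciprocal"}.
#' @param T_range Search range for cycle length, hours (quadrature model).
#' @return Object of class \code{"cycle_length_ratio"}: \code{ratio}
#'   (T_sample / T_reference), \code{model}, and for the quadrature model
#'   \code{T_sample}, \code{T_reference}.
#' @export
relative_cycle_length <- function(sample, reference, tau = 1.5,
                                  model = c("quadrature", "reciprocal"),
                                  T_range = c(NA, 2000)) {
  stopifnot(inherits(sample, "ft_summary"), inherits(reference, "ft_summary"))
  model <- match.arg(model)
  check_scalar_num(tau, "tau", positive = TRUE)
  if (model == "reciprocal") {
    if (sample$median_ratio <= 0) stopf("sample median ratio must be positive")
    return(structure(list(ratio = reference$median_ratio / sample$median_ratio,
                          model = model, T_sample = NA_real_,
                          T_reference = NA_real_),
                     class = "cycle_length_ratio"))
  }
  t_lo <- if (is.na(T_range[1])) tau * 1.001 else T_range[1]
  t_hi <- T_range[2]
  r_hi <- ft_median_model(t_lo, tau)   # ratio at shortest cycle (largest)
  r_lo <- ft_median_model(t_hi, tau)
  invert <- function(r) {
    if (r > r_hi || r < r_lo)
      stopf("median ratio %.4f outside attainable range [%.4f, %.4f] for tau = %g, T in [%.3g, %.3g] h",
            r, r_lo, r_hi, tau, t_lo, t_hi)
    stats::uniroot(function(T) ft_median_model(T, tau) - r,
                   lower = t_lo, upper = t_hi, tol = 1e-6)$root
  }
  T_s <- invert(sample$median_ratio)
  T_r <- invert(reference$median_ratio)
  structure(list(ratio = T_s / T_r, model = model,
                 T_sample = T_s, T_reference = T_r),
            class = "cycle_length_ratio")
}

#' @export
print.cycle_length_ratio <- function(x, ...) {
  cat(sprintf("Relative cell-cycle length (%s model): %.3f\n", x$model, x$ratio))
  if (x$model == "quadrature")
    cat(sprintf("  T_sample = %.3g h, T_reference = %.3g h\n",
                x$T_sample, x$T_reference))
  invisible(x)
}

#' Ergodic stage-duration inference
#'
#' At steady state, with constant flux through a multi-stage process, the
#' number of cells observed in a stage in a snapshot is proportional to the
#' time cells spend in that stage.  Relative durations are therefore the
#' normalized occupancy counts.
#'
#' @param stage_counts Nonnegative integer occupancy counts (>= 2 stages).
#' @return Object of class \code{"stage_durations"}:
#'   \code{relative_durations} (sum to 1), \code{counts}.
#' @export
ergodic_durations <- function(stage_counts) {
  if (length(stage_counts) < 2L) stopf("need >= 2 stages")
  if (any(stage_counts < 0)) stopf("counts must be nonnegative")
  total <- sum(stage_counts)
  if (total == 0) stopf("all-zero counts")
  if (any(stage_counts == 0))
    warnf("zero-count stage(s) assigned zero duration")
  structure(list(relative_durations = stage_counts / total,
                 counts = stage_counts),
            class = "stage_durations")
}

#' @export
print.stage_durations <- function(x, ...) {
  cat("Relative stage durations (ergodic):",
      paste(sprintf("%.3f", x$relative_durations), collapse = ", "), "\n")
  invisible(x)
}
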