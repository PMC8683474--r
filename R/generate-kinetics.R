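#' Growth ground truth
#'
#' Parameters of an exponentially growing culture: initial cell number,
#' doubling time, and lognormal count-observation noise.  The default
#' doubling time of 6.1 h corresponds to EpoR-rescued early erythroblasts;
#' use 8.6 h for the survival-only (Bcl-xL) arm.
#'
#' @param n0 Initial cell count.
#' @param doubling_time Doubling time, hours.
#' @param count_cv Observation-noise coefficient of variation.
#' @return An object of class \code{"growth_truth"}.
#' @export
growth_truth <- function(n0 = 1e5, doubling_time = 6.1, count_cv = 0.1) {
  check_scalar_num(n0, "n0", positive = TRUE)
  check_scalar_num(doubling_time, "doubling_time", positive = TRUE)
  check_scalar_num(count_cv, "count_cv")
  if (count_cv < 0) stopf("'count_cv' must be >= 0")
  structure(list(n0 = n0, doubling_time = doubling_time, count_cv = count_cv),
            class = "growth_truth")
}

#' Generate a growth-count time series
#'
#' Counts follow \eqn{n_0 \cdot 2^{t/T_d}} with multiplicative lognormal
#' noise.  A relative-count column (relative to the observed count at the
#' first timepoint) is included, matching how growth curves are usually
#' reported.
#'
#' @param truth A [growth_truth()].
#' @param times Sampling times in hours, sorted, nonnegative.
#' @param seed Integer seed.
#' @return Data frame with \code{time_h, count, rel_count, true_count} and
#'   attribute \code{"truth"}.
#' @export
gen_growth_series <- function(truth = growth_truth(), times = seq(0, 48, by = 4),
                              seed = 1L) {
  stopifnot(inherits(truth, "growth_truth"))
  if (length(times) == 0L) stopf("'times' must be non-empty")
  if (is.unsorted(times) || any(times < 0))
    stopf("'times' must be sorted and nonnegative")
  set.seed(seed)
  true_count <- truth$n0 * 2^(times / truth$doubling_time)
  count <- true_count * lnorm_mult(length(times), truth$count_cv)
  out <- data.frame(time_h = times, count = count,
                    rel_count = count / count[1L], true_count = true_count)
  attr(out, "truth") <- truth
  out
}

#' Generate bivariate BrdU/DNA cell-cycle data
#'
#' Emulates a 30-min BrdU pulse read out against DNA content: G1 cells sit in
#' a Gaussian 2N cluster, G2/M in a Gaussian 4N cluster, and S-phase cells are
#' uniform in DNA content between 2N and 4N with BrdU incorporation
#' proportional to the intra-S-phase DNA synthesis rate \code{s_speed}.
#' Non-S cells carry antibody background only.
#'
#' @param fractions Length-3 nonnegative vector \code{(fG1, fS, fG2M)} summing
#'   to 1.
#' @param s_speed Relative intra-S-phase synthesis rate; the S-phase BrdU
#'   median scales linearly with it.
#' @param n Number of events.
#' @param seed Integer seed.
#' @param dna_2n DNA-content units of the 2N peak.
#' @param dna_cv CV of the 2N/4N Gaussian clusters.
#' @param brdu_background Median background BrdU intensity.
#' @param brdu_s_level Median S-phase BrdU intensity at \code{s_speed = 1}.
#' @return Data frame with \code{dna, brdu, true_phase} and attribute
#'   \code{"fractions"}.
#' @export
gen_brdu_dna <- function(fractions, s_speed = 1, n = 10000L, seed = 1L,
                         dna_2n = 100, dna_cv = 0.04,
                         brdu_background = 10, brdu_s_level = 200) {
  if (length(fractions) != 3L || any(fractions < 0))
    stopf("'fractions' must be 3 nonnegative numbers (G1, S, G2M)")
  if (abs(sum(fractions) - 1) > 1e-8)
    stopf("'fractions' must sum to 1")
  if (length(n) != 1L || n <= 0) stopf("'n' must be a positive integer")
  check_scalar_num(s_speed, "s_speed", positive = TRUE)
  set.seed(seed)
  n <- as.integer(n)
  phase <- sample(c("g1", "s", "g2m"), n, replace = TRUE, prob = fractions)
  dna <- numeric(n)
  brdu <- numeric(n)
  for (ph in c("g1", "s", "g2m")) {
    sel <- phase == ph
    m <- sum(sel)
    if (m == 0) next
    dna[sel] <- switch(ph,
      g1  = stats::rnorm(m, dna_2n, dna_2n * dna_cv),
      s   = stats::runif(m, dna_2n, 2 * dna_2n),
      g2m = stats::rnorm(m, 2 * dna_2n, 2 * dna_2n * dna_cv))
    brdu[sel] <- if (ph == "s")
      stats::rlnorm(m, log(brdu_s_level * s_speed), 0.25)
    else
      stats::rlnorm(m, log(brdu_background), 0.3)
  }
  out <- data.frame(dna = dna, brdu = brdu, true_phase = phase)
  attr(out, "fractions") <- fractions
  out
}

#' Fluorescent-timer ground truth
#'
#' Parameters of the H2B fluorescent-timer model: the timer fluoresces blue
#' for \code{tau} hours after synthesis, then matures to red.  Histone
#' content doubles over one cycle of length \code{T} (constant synthesis rate
#' \eqn{k = H_0/T}), so for a cell of cycling age \eqn{a}: blue
#' \eqn{= k\,\min(a, \tau)}, total \eqn{= H_0 + k a}.
#'
#' @param T Cell-cycle length, hours.
#' @param tau Blue-to-red maturation time, hours; \code{0 < tau < T}.
#' @param noise_cv Lognormal channel-noise CV.
#' @return An object of class \code{"ft_truth"}.
#' @export
ft_truth <- function(T = 6, tau = 1.5, noise_cv = 0.05) {
  check_scalar_num(T, "T", positive = TRUE)
  check_scalar_num(tau, "tau", positive = TRUE)
  if (tau >= T) stopf("'tau' must be < T (got tau=%g, T=%g)", tau, T)
  check_scalar_num(noise_cv, "noise_cv")
  if (noise_cv < 0) stopf("'noise_cv' must be >= 0")
  structure(list(T = T, tau = tau, noise_cv = noise_cv), class = "ft_truth")
}

# Steady-state cycling-age density f(a) = (2 ln 2 / T) 2^(-a/T) on [0, T]:
# exponentially growing populations are enriched for young cells.  Inverse
# CDF used for sampling; exported for quadrature oracles in tests.
#' Cycling-age density and sampler at steady state
#'
#' In an unsynchronized, exponentially growing population the density of
#' cycling age \eqn{a \in [0, T]} is \eqn{f(a) = (2\ln 2/T)\,2^{-a/T}}.
#' \code{ft_age_density} evaluates it; \code{ft_age_quantile} is its inverse
#' CDF, \eqn{a(u) = -T \log_2(1 - u/2)}.
#'
#' @param a Ages (hours).
#' @param u Probabilities in \code{[0, 1]}.
#' @param T Cycle length (hours).
#' @return Numeric vector.
#' @export
ft_age_density <- function(a, T) {
  ifelse(a < 0 | a > T, 0, (2 * log(2) / T) * 2^(-a / T))
}

#' @rdname ft_age_density
#' @export
ft_age_quantile <- function(u, T) {
  -T * log2(1 - u / 2)
}

#' Generate fluorescent-timer (blue/red) events
#'
#' Samples cycling ages from the steady-state age density and converts them
#' to blue and red channel intensities under the timer model of
#' [ft_truth()], with multiplicative lognormal channel noise.
#'
#' @param truth An [ft_truth()].
#' @param n Number of cells.
#' @param seed Integer seed.
#' @param h0 Histone content at birth (arbitrary units).
#' @return Data frame with \code{blue, red, true_age} and attribute
#'   \code{"truth"}.
#' @export
gen_ft_events <- function(truth = ft_truth(), n = 10000L, seed = 1L, h0 = 100) {
  stopifnot(inherits(truth, "ft_truth"))
  if (length(n) != 1L || n <= 0) stopf("'n' must be a positive integer")
  set.seed(seed)
  n <- as.integer(n)
  a <- ft_age_quantile(stats::runif(n), truth$T)
  k <- h0 / truth$T
  blue <- k * pmin(a, truth$tau) * lnorm_mult(n, truth$noise_cv)
  total_noiseless <- h0 + k * a
  red <- (total_noiseless - k * pmin(a, truth$tau)) * lnorm_mult(n, truth$noise_cv)
  out <- data.frame(blue = blue, red = red, true_age = a)
  attr(out, "truth") <- truth
  out
}

#' Simulate a steady-state snapshot of a multi-stage process
#'
#' Cells enter stage 1 as a Poisson stream of constant rate, advance to the
#' next stage after that stage's fixed duration, and exit after the last.
#' The snapshot is taken after a burn-in of at least three total transit
#' times, so occupancy has reached steady state.  Under the ergodic
#' principle, expected occupancy is proportional to stage duration.
#'
#' @param durations Positive stage durations (hours).
#' @param n Expected number of cells present in the snapshot.
#' @param seed Integer seed.
#' @return Integer vector of per-stage occupancy counts (named if
#'   \code{durations} is named).
#' @export
gen_snapshot <- function(durations, n = 10000L, seed = 1L) {
  if (length(durations) < 1L || any(durations <= 0))
    stopf("'durations' must be positive")
  if (length(n) != 1L || n <= 0) stopf("'n' must be a positive integer")
  set.seed(seed)
  total <- sum(durations)
  t_snap <- 4 * total                       # burn-in 3*total + one transit
  rate <- n / total
  n_arrivals <- stats::rpois(1, rate * t_snap)
  arrival <- stats::runif(n_arrivals, 0, t_snap)
  age <- t_snap - arrival
  present <- age < total
  stage <- findInterval(age[present], cumsum(durations), left.open = FALSE) + 1L
  counts <- tabulate(stage, nbins = length(durations))
  names(counts) <- names(durations)
  counts
}
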