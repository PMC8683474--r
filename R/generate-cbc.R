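#' Intervention-study cohort design
#'
#' Describes a placebo-controlled Epo intervention study: group sizes, the
#' baseline / treatment / follow-up windows, the sampling interval, per-analyte
#' baseline distributions, and per-analyte treatment-effect time profiles.
#' Defaults mirror a study with 25 treated and 9 placebo subjects, 4 baseline
#' weeks, 3 treatment weeks and 5 follow-up weeks of weekly sampling, in which
#' hemoglobin rises by 5% over baseline during treatment, the reticulocyte
#' count rises during treatment and then dips below baseline after cessation,
#' and MCV (with RDW-SD) rises and persists beyond the treatment period.
#'
#' Effect profiles are piecewise-linear in time (days from treatment start)
#' and are identically zero (additive) or one (multiplicative) before day 0.
#'
#' @param n_treated,n_placebo Subject counts.
#' @param baseline_weeks,treatment_weeks,followup_weeks Window durations.
#' @param sampling_interval Days between samplings.
#' @param analyte_baselines Data frame with columns \code{analyte, mean,
#'   between_sd, within_sd}.
#' @param treatment_effects Named list (by analyte) of lists with fields
#'   \code{type} (\code{"additive"} or \code{"multiplicative"}) and
#'   \code{breaks} (data frame \code{time_days, value}).
#' @return An object of class \code{"cohort_design"}.
#' @export
cohort_design <- function(n_treated = 25L, n_placebo = 9L,
                          baseline_weeks = 4L, treatment_weeks = 3L,
                          followup_weeks = 5L, sampling_interval = 7L,
                          analyte_baselines = NULL, treatment_effects = NULL) {
  for (v in c(n_treated, n_placebo, baseline_weeks, treatment_weeks,
              followup_weeks, sampling_interval))
    if (length(v) != 1L || v <= 0) stopf("all counts and durations must be positive")
  if (is.null(analyte_baselines))
    analyte_baselines <- data.frame(
      analyte    = c("mcv", "rdw_sd", "retic", "hemoglobin"),
      mean       = c(90, 42, 60, 14.5),
      between_sd = c(3, 2.5, 12, 0.9),
      within_sd  = c(0.7, 0.8, 6, 0.25))
  t_end <- (treatment_weeks + followup_weeks) * 7
  t_tx <- treatment_weeks * 7
  if (is.null(treatment_effects))
    treatment_effects <- list(
      mcv = list(type = "additive", breaks = data.frame(
        time_days = c(0, t_tx, t_end), value = c(0, 4, 3.5))),
      rdw_sd = list(type = "additive", breaks = data.frame(
        time_days = c(0, t_tx, t_end), value = c(0, 2.5, 2))),
      retic = list(type = "additive", breaks = data.frame(
        time_days = c(0, 7, t_tx, t_tx + 3, t_tx + 17, t_tx + 28, t_end),
        value     = c(0, 25, 25, -15, -15, 0, 0))),
      hemoglobin = list(type = "multiplicative", breaks = data.frame(
        time_days = c(0, 5, t_tx, t_tx + 7, t_tx + 21, t_end),
        value     = c(1, 1.05, 1.05, 1.02, 1, 1))))
  structure(list(n_treated = as.integer(n_treated),
                 n_placebo = as.integer(n_placebo),
                 baseline_weeks = baseline_weeks,
                 treatment_weeks = treatment_weeks,
                 followup_weeks = followup_weeks,
                 sampling_interval = sampling_interval,
                 analyte_baselines = analyte_baselines,
                 treatment_effects = treatment_effects),
            class = "cohort_design")
}

#' Generate a synthetic CBC subject panel
#'
#' Simulates a long-format complete-blood-count panel: one row per subject,
#' timepoint and analyte.  Each subject draws a persistent baseline level
#' (between-subject variation); each sampling adds within-subject noise.
#' Treated subjects additionally receive the design's effect profile from
#' treatment start (day 0) onward; placebo subjects receive noise only.
#' The \code{true_effect} column records the expected deviation from the
#' subject's baseline in analyte units (0 for placebo and baseline rows).
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed.
#' @return Data frame with columns \code{subject_id, group, time_days,
#'   analyte, value, true_effect}.
#' @export
gen_cbc_panel <- function(design = cohort_design(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  if (design$n_treated + design$n_placebo <= 0) stopf("zero subjects")
  set.seed(seed)
  times <- seq(-design$baseline_weeks * 7,
               (design$treatment_weeks + design$followup_weeks) * 7,
               by = design$sampling_interval)
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(design$n_treated + design$n_placebo)),
    group = rep(c("treated", "placebo"),
                c(design$n_treated, design$n_placebo)))
  ab <- design$analyte_baselines
  rows <- vector("list", nrow(ab))
  for (i in seq_len(nrow(ab))) {
    an <- ab$analyte[i]
    base_subj <- stats::rnorm(nrow(subjects), ab$mean[i], ab$between_sd[i])
    eff <- design$treatment_effects[[an]]
    eff_fun <- if (is.null(eff)) function(t) rep(0, length(t)) else
      profile_fun(eff$breaks,
                  default = if (eff$type == "multiplicative") 1 else 0)
    grid <- expand.grid(si = seq_len(nrow(subjects)), time_days = times)
    base <- base_subj[grid$si]
    treated <- subjects$group[grid$si] == "treated"
    post <- grid$time_days >= 0
    raw_eff <- eff_fun(grid$time_days)
    delta <- if (!is.null(eff) && eff$type == "multiplicative")
      base * (raw_eff - 1) else raw_eff
    delta[!treated | !post] <- 0
    value <- base + delta +
      stats::rnorm(nrow(grid), 0, ab$within_sd[i])
    rows[[i]] <- data.frame(
      subject_id = subjects$subject_id[grid$si],
      group = subjects$group[grid$si],
      time_days = grid$time_days, analyte = an,
      value = value, true_effect = delta)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$analyte, out$subject_id, out$time_days), ]
  rownames(out) <- NULL
  attr(out, "design") <- design
  out
}
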