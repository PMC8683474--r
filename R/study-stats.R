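#' Subject-level baseline correction
#'
#' Replaces each value by its deviation from the subject's own mean baseline
#' (timepoints with \code{time_days < 0}) for that analyte, removing
#' between-subject level differences before group contrasts.  Baseline rows
#' are retained (their corrected values are deviations from the same mean)
#' and the per-row baseline mean is kept for audit.
#'
#' @param panel Long-format data frame with columns \code{subject_id, group,
#'   time_days, analyte, value}.
#' @return The panel with added columns \code{baseline_mean},
#'   \code{corrected}, \code{is_baseline}.
#' @export
baseline_correct <- function(panel) {
  need <- c("subject_id", "time_days", "analyte", "value")
  if (!all(need %in% names(panel)))
    stopf("panel must have columns %s", paste(need, collapse = ", "))
  key <- interaction(panel$subject_id, panel$analyte, drop = TRUE)
  is_base <- panel$time_days < 0
  has_base <- tapply(is_base, key, any)
  if (!all(has_base)) {
    bad <- unique(sub("\\..*$", "", names(has_base)[!has_base]))
    stopf("subject(s) lacking baseline records: %s",
          paste(bad, collapse = ", "))
  }
  bmean_by_key <- tapply(panel$value[is_base], key[is_base], mean)
  panel$baseline_mean <- as.numeric(bmean_by_key[as.character(key)])
  panel$corrected <- panel$value - panel$baseline_mean
  panel$is_baseline <- is_base
  panel
}

#' Fractional change from baseline
#'
#' Per subject and analyte: \code{value / baseline_mean - 1}, the scale on
#' which multi-analyte intervention time courses are overlaid.
#'
#' @param panel As in [baseline_correct()].
#' @return The panel with added columns \code{baseline_mean},
#'   \code{frac_change}, \code{is_baseline}.
#' @export
fractional_change <- function(panel) {
  panel <- baseline_correct(panel)
  if (any(panel$baseline_mean == 0))
    stopf("zero baseline mean: fractional change undefined")
  panel$frac_change <- panel$value / panel$baseline_mean - 1
  panel$corrected <- NULL
  panel
}

#' Correlate two analytes across a panel
#'
#' Pools all (subject, timepoint) samples carrying both analytes
#' (\code{scope = "pooled"}), or computes the within-subject correlation per
#' subject and reports the mean r (\code{scope = "per_subject"}; its p-value
#' is a two-sided one-sample t test of the per-subject Fisher-z values
#' against zero).
#'
#' @param panel As in [baseline_correct()].
#' @param analyte_x,analyte_y Analyte names.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param scope \code{"pooled"} or \code{"per_subject"}.
#' @return Object of class \code{"correlation_result"}: \code{r}, \code{p},
#'   \code{n} (pairs or subjects), \code{method}, \code{scope}.
#' @export
correlate <- function(panel, analyte_x, analyte_y,
                      method = c("pearson", "spearman"),
                      scope = c("pooled", "per_subject")) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  x <- panel[panel$analyte == analyte_x, c("subject_id", "time_days", "value")]
  y <- panel[panel$analyte == analyte_y, c("subject_id", "time_days", "value")]
  m <- merge(x, y, by = c("subject_id", "time_days"),
             suffixes = c("_x", "_y"))
  if (scope == "pooled") {
    if (nrow(m) < 3L) stopf("need >= 3 complete pairs, got %d", nrow(m))
    ct <- suppressWarnings(
      stats::cor.test(m$value_x, m$value_y, method = method))
    res <- list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m),
                method = method, scope = scope)
  } else {
    rs <- vapply(split(m, m$subject_id), function(d) {
      if (nrow(d) < 3L || stats::sd(d$value_x) == 0 || stats::sd(d$value_y) == 0)
        return(NA_real_)
      suppressWarnings(stats::cor(d$value_x, d$value_y, method = method))
    }, numeric(1))
    rs <- rs[is.finite(rs)]
    if (length(rs) < 3L) stopf("need >= 3 subjects with computable r")
    z <- atanh(pmin(pmax(rs, -1 + 1e-12), 1 - 1e-12))
    tt <- stats::t.test(z)
    res <- list(r = mean(rs), p = tt$p.value, n = length(rs),
                method = method, scope = scope)
  }
  structure(res, class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation (%s): r = %.3f, p = %.3g, n = %d\n",
              x$method, x$scope, x$r, x$p, x$n))
  invisible(x)
}

#' Welch two-sample t test from summary statistics
#'
#' The unequal-variance two-sample t test computed from group means, SDs and
#' sizes: \eqn{t = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}} with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.  Useful
#' when only printed summaries are available.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @param conf_level Confidence level for the difference (default 0.95).
#' @return Object of class \code{"test_result"}: \code{statistic}, \code{df},
#'   \code{p}, \code{estimate} (m1 - m2), \code{ci}.
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2, conf_level = 0.95) {
  for (v in list(n1 = n1, n2 = n2))
    if (v < 2) stopf("group sizes must be >= 2")
  if (s1 <= 0 || s2 <= 0) stopf("group SDs must be > 0")
  se2_1 <- s1^2 / n1
  se2_2 <- s2^2 / n2
  se <- sqrt(se2_1 + se2_2)
  t <- (m1 - m2) / se
  df <- (se2_1 + se2_2)^2 / (se2_1^2 / (n1 - 1) + se2_2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(list(statistic = t, df = df, p = p, estimate = m1 - m2,
                 ci = c(m1 - m2 - q * se, m1 - m2 + q * se),
                 method = "Welch two-sample t (summary statistics)"),
            class = "test_result")
}

#' Paired t test on keyed measurements
#'
#' One-sample t test on within-pair differences, pairing the two vectors by
#' shared keys (e.g. experiment or animal identifiers).
#'
#' @param values_a,values_b Numeric vectors.
#' @param keys_a,keys_b Pairing keys; every key must appear in both.
#' @return Object of class \code{"test_result"}.
#' @export
paired_t <- function(values_a, values_b, keys_a = seq_along(values_a),
                     keys_b = seq_along(values_b)) {
  if (length(values_a) != length(keys_a) || length(values_b) != length(keys_b))
    stopf("values and keys must have equal length")
  unmatched <- c(setdiff(keys_a, keys_b), setdiff(keys_b, keys_a))
  if (length(unmatched))
    stopf("unmatched pairing keys: %s", paste(unique(unmatched), collapse = ", "))
  ord <- match(keys_a, keys_b)
  d <- values_a - values_b[ord]
  if (length(d) < 2L) stopf("need >= 2 complete pairs")
  if (stats::sd(d) == 0)
    stopf("all pair differences identical: t test undefined")
  tt <- stats::t.test(d)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, estimate = unname(tt$estimate),
                 ci = as.numeric(tt$conf.int), method = "paired t"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: t = %.3f, df = %.1f, p = %.3g\n", x$method, x$statistic,
              x$df, x$p))
  cat(sprintf("  estimate %.4g (95%% CI %.4g to %.4g)\n",
              x$estimate, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector; adjusted
#' values are order-preserving and never smaller than the raw values.
#'
#' @param pvalues P-values in \code{(0, 1]}.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) stopf("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-timepoint treated-vs-placebo contrasts
#'
#' Baseline-corrects the panel, then at each post-baseline timepoint compares
#' treated and placebo corrected values for one analyte by the Welch test,
#' adjusting the per-timepoint p-values across timepoints by
#' Benjamini-Hochberg.  This is a deliberately simple analogue of a
#' mixed-model contrast analysis: the subject random intercept is absorbed by
#' the baseline correction.
#'
#' @param panel As in [baseline_correct()], with a \code{group} column of
#'   \code{"treated"} / \code{"placebo"}.
#' @param analyte Analyte to test.
#' @return Data frame: one row per timepoint with \code{time_days,
#'   n_treated, n_placebo, estimate, statistic, df, p, p_adj}.
#' @export
per_timepoint_contrasts <- function(panel, analyte) {
  if (!"group" %in% names(panel)) stopf("panel must have a 'group' column")
  p <- baseline_correct(panel[panel$analyte == analyte, , drop = FALSE])
  p <- p[p$time_days >= 0, , drop = FALSE]
  times <- sort(unique(p$time_days))
  rows <- list()
  for (tp in times) {
    d <- p[p$time_days == tp, ]
    a <- d$corrected[d$group == "treated"]
    b <- d$corrected[d$group == "placebo"]
    if (length(a) < 2L || length(b) < 2L) {
      warnf("timepoint %g skipped: fewer than 2 subjects in a group", tp)
      next
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate noiseless case: identical groups are a clean null
      if (mean(a) != mean(b))
        stopf("timepoint %g: zero variance with unequal means", tp)
      rows[[length(rows) + 1L]] <- data.frame(
        time_days = tp, n_treated = length(a), n_placebo = length(b),
        estimate = 0, statistic = 0, df = NA_real_, p = 1)
      next
    }
    tt <- stats::t.test(a, b)   # Welch by default
    rows[[length(rows) + 1L]] <- data.frame(
      time_days = tp, n_treated = length(a), n_placebo = length(b),
      estimate = unname(diff(rev(tt$estimate))),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value)
  }
  if (!length(rows)) stopf("no testable timepoints")
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}
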