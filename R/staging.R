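#' Quintile maturation staging by nuclear offset
#'
#' The nuclear offset rises continuously through erythroid terminal
#' differentiation, so its quintiles in a reference (e.g. saline-injected)
#' sample define five maturational stages.  The reference 20/40/60/80th
#' percentiles become fixed edges that are then applied unchanged to every
#' query sample, allowing like-for-like comparison of a feature (typically
#' cell diameter) across treatments at matched maturational stage.
#'
#' Values equal to an edge are assigned to the lower bin; this tie rule makes
#' assignment a pure function of (edges, value).
#'
#' @param reference Numeric vector of nuclear offsets defining the edges
#'   (\code{n >= 50}).
#' @param queries Named list of numeric offset vectors, one per sample.
#' @param feature Optional named list (same names and lengths as
#'   \code{queries}) of per-event feature values to summarize per bin;
#'   defaults to the offsets themselves.
#' @return Object of class \code{"quintile_staging"}: \code{edges} (4 cuts),
#'   \code{assignments} (named list of per-event bins 1-5), and
#'   \code{summary}, a data frame of per sample x bin counts and median
#'   feature.
#' @export
quintile_stage <- function(reference, queries, feature = NULL) {
  if (length(reference) < 50L)
    stopf("reference sample must have >= 50 events, got %d", length(reference))
  if (is.null(names(queries)) || any(!nzchar(names(queries))))
    stopf("'queries' must be a named list")
  if (is.null(feature)) feature <- queries
  if (!identical(names(feature), names(queries)))
    stopf("'feature' must have the same sample names as 'queries'")
  edges <- stats::quantile(reference, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  if (any(diff(edges) <= 0))
    stopf("reference quintile edges are not strictly increasing (heavy ties)")
  assignments <- list()
  rows <- list()
  for (s in names(queries)) {
    x <- queries[[s]]
    fv <- feature[[s]]
    if (length(x) == 0L) {
      warnf("query sample '%s' is empty: omitted", s)
      next
    }
    if (length(fv) != length(x))
      stopf("feature for sample '%s' has length %d, expected %d",
            s, length(fv), length(x))
    bin <- assign_bins(x, edges)
    assignments[[s]] <- bin
    rows[[s]] <- data.frame(
      sample = s, bin = 1:5,
      n = tabulate(bin, nbins = 5),
      median_feature = vapply(1:5, function(b)
        if (any(bin == b)) stats::median(fv[bin == b]) else NA_real_,
        numeric(1)))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(edges = edges, assignments = assignments, summary = summary),
            class = "quintile_staging")
}

#' @export
print.quintile_staging <- function(x, ...) {
  cat("Nuclear-offset quintile staging\n")
  cat("  edges:", paste(sprintf("%.4g", x$edges), collapse = ", "), "\n")
  print(x$summary)
  invisible(x)
}

#' Composite-quantile mean-diameter ratio heatmap
#'
#' Bins every event by the pooled (across-sample) quantiles of two reporter
#' channels (e.g. hCD4 and GFP), then computes the mean of a value column
#' (cell diameter) within each composite bin for each sample, and finally the
#' ratio of those per-bin means against a designated reference sample.  This
#' controls a size comparison for reporter expression level.
#'
#' Empty composite bins are reported as \code{NA}, never zero.
#'
#' @param samples Named list of data frames, each carrying the two channel
#'   columns and the value column.
#' @param chA,chB Channel column names (default \code{"hcd4"}, \code{"gfp"}).
#' @param value Value column name (default \code{"diameter"}).
#' @param k Bins per channel (default 5, \code{k >= 2}).
#' @param reference Name of the reference sample in \code{samples}.
#' @return List with \code{edges_a}, \code{edges_b} (pooled interior edges),
#'   \code{means} (named list of k x k matrices, rows = chA bin, cols = chB
#'   bin), and \code{ratios} (named list of k x k matrices sample/reference,
#'   reference omitted).
#' @export
composite_quantile_ratio <- function(samples, chA = "hcd4", chB = "gfp",
                                     value = "diameter", k = 5, reference) {
  if (k < 2) stopf("'k' must be >= 2")
  if (is.null(names(samples))) stopf("'samples' must be a named list")
  if (missing(reference) || !reference %in% names(samples))
    stopf("reference sample absent from 'samples'")
  for (s in names(samples))
    if (!all(c(chA, chB, value) %in% names(samples[[s]])))
      stopf("sample '%s' lacks columns %s", s,
            paste(setdiff(c(chA, chB, value), names(samples[[s]])),
                  collapse = ", "))
  pooled_a <- unlist(lapply(samples, `[[`, chA), use.names = FALSE)
  pooled_b <- unlist(lapply(samples, `[[`, chB), use.names = FALSE)
  probs <- seq_len(k - 1) / k
  edges_a <- stats::quantile(pooled_a, probs, names = FALSE)
  edges_b <- stats::quantile(pooled_b, probs, names = FALSE)
  means <- lapply(samples, function(df) {
    ba <- assign_bins(df[[chA]], edges_a)
    bb <- assign_bins(df[[chB]], edges_b)
    m <- matrix(NA_real_, k, k)
    agg <- tapply(df[[value]], list(factor(ba, 1:k), factor(bb, 1:k)),
                  mean)
    m[] <- agg
    m
  })
  ref_m <- means[[reference]]
  ratios <- lapply(means[setdiff(names(means), reference)],
                   function(m) m / ref_m)
  list(edges_a = edges_a, edges_b = edges_b, means = means, ratios = ratios)
}

#' Expression vs cell-size dose-response
#'
#' Bins events by quantiles of a reporter's expression level and summarizes
#' the median expression and median cell diameter per bin, then reports the
#' Spearman rank correlation of the per-bin medians.  A monotone relationship
#' across bins is the signature of classical dose-response kinetics of
#' receptor expression on cell size.
#'
#' @param expression Per-event expression values (a.u.).
#' @param diameter Per-event cell diameters (um).
#' @param n_bins Number of quantile bins (\code{>= 4}); needs at least
#'   \code{10 * n_bins} events.
#' @return List with \code{bins} (data frame: bin, n, median_expression,
#'   median_diameter), \code{rho}, \code{p}.
#' @export
expression_size_response <- function(expression, diameter, n_bins = 6) {
  if (n_bins < 4) stopf("'n_bins' must be >= 4")
  n <- length(expression)
  if (length(diameter) != n) stopf("inputs must have equal length")
  if (n < 10 * n_bins)
    stopf("need >= %d events for %d bins, got %d", 10 * n_bins, n_bins, n)
  if (stats::sd(expression) == 0) stopf("constant expression: undefined bins")
  edges <- stats::quantile(expression, seq_len(n_bins - 1) / n_bins,
                           names = FALSE)
  bin <- assign_bins(expression, edges)
  bins <- data.frame(
    bin = seq_len(n_bins),
    n = tabulate(bin, nbins = n_bins),
    median_expression = vapply(seq_len(n_bins), function(b)
      stats::median(expression[bin == b]), numeric(1)),
    median_diameter = vapply(seq_len(n_bins), function(b)
      stats::median(diameter[bin == b]), numeric(1)))
  ct <- suppressWarnings(
    stats::cor.test(bins$median_expression, bins$median_diameter,
                    method = "spearman"))
  list(bins = bins, rho = unname(ct$estimate), p = ct$p.value)
}
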