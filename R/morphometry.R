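#' Morphometry of a cell/nucleus mask pair
#'
#' Computes the per-cell morphometric features underlying the nuclear-offset
#' statistic: mask areas, intensity-weighted centroids of the cell image
#' (e.g. CD71 fluorescence) and the nucleus image (e.g. Draq5), the delta
#' centroid (Euclidean distance between the two centroids, um), cell and
#' nuclear diameters, and the nuclear offset = delta centroid / cell diameter.
#'
#' Diameters come from the bead calibration applied to the mask area in px^2
#' when \code{cal} is supplied, otherwise from the equivalent-disc formula
#' \eqn{d = 2\sqrt{A/\pi}}; the path used is recorded in
#' \code{diameter_method}.
#'
#' @param cell_mask,nuc_mask Label matrices (same shape, nonzero = inside).
#' @param cell_img,nuc_img Optional intensity matrices for centroid weighting;
#'   defaults to the masks themselves (uniform weighting).
#' @param pixel_size Micrometers per pixel.
#' @param cal Optional [fit_bead_calibration()] result.
#' @return Object of class \code{"mask_features"}: \code{cell_area},
#'   \code{nuc_area} (um^2), \code{cell_diameter}, \code{nuc_diameter} (um),
#'   \code{cell_centroid}, \code{nuc_centroid} (um), \code{delta_centroid}
#'   (um), \code{nuclear_offset}, \code{diameter_method}.
#' @export
mask_features <- function(cell_mask, nuc_mask, cell_img = NULL, nuc_img = NULL,
                          pixel_size, cal = NULL) {
  if (!identical(dim(cell_mask), dim(nuc_mask)))
    stopf("cell and nucleus masks must have the same shape")
  check_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  if (is.null(cell_img)) cell_img <- cell_mask * 1.0
  if (is.null(nuc_img)) nuc_img <- nuc_mask * 1.0
  if (!identical(dim(cell_img), dim(cell_mask)) ||
      !identical(dim(nuc_img), dim(nuc_mask)))
    stopf("intensity images must match the mask shape")

  centroid <- function(mask, img) {
    w <- img * (mask > 0)
    tot <- sum(w)
    if (tot <= 0) stopf("empty mask (or zero intensity inside mask)")
    # pixel centers: x along columns, y along rows
    xs <- (col(mask) - 0.5) * pixel_size
    ys <- (row(mask) - 0.5) * pixel_size
    c(x = sum(w * xs) / tot, y = sum(w * ys) / tot)
  }
  c_cell <- centroid(cell_mask, cell_img)
  c_nuc <- centroid(nuc_mask, nuc_img)
  cell_area_px <- sum(cell_mask > 0)
  nuc_area_px <- sum(nuc_mask > 0)
  if (cell_area_px == 0 || nuc_area_px == 0) stopf("empty mask")
  cell_area <- cell_area_px * pixel_size^2
  nuc_area <- nuc_area_px * pixel_size^2

  if (is.null(cal)) {
    cell_d <- 2 * sqrt(cell_area / pi)
    nuc_d <- 2 * sqrt(nuc_area / pi)
    method <- "equivalent_disc"
  } else {
    cell_d <- as.numeric(area_to_diameter(cal, cell_area_px))
    nuc_d <- as.numeric(area_to_diameter(cal, nuc_area_px))
    method <- "bead_calibration"
  }
  delta <- sqrt(sum((c_cell - c_nuc)^2))
  structure(list(cell_area = cell_area, nuc_area = nuc_area,
                 cell_diameter = cell_d, nuc_diameter = nuc_d,
                 cell_centroid = c_cell, nuc_centroid = c_nuc,
                 delta_centroid = delta,
                 nuclear_offset = delta / cell_d,
                 diameter_method = method),
            class = "mask_features")
}

#' @export
print.mask_features <- function(x, ...) {
  cat(sprintf("Mask features (%s diameters)\n", x$diameter_method))
  cat(sprintf("  cell: area %.2f um^2, diameter %.2f um\n",
              x$cell_area, x$cell_diameter))
  cat(sprintf("  nucleus: area %.2f um^2, diameter %.2f um\n",
              x$nuc_area, x$nuc_diameter))
  cat(sprintf("  delta centroid %.3f um, nuclear offset %.4f\n",
              x$delta_centroid, x$nuclear_offset))
  invisible(x)
}

#' Map CD71 mask area to brightfield area
#'
#' The brightfield area mask is the size standard, but some acquisitions only
#' carry the CD71 fluorescence mask.  This fits the least-squares line of
#' brightfield area on CD71 area over events carrying both, and imputes the
#' mapped brightfield area for events lacking it, so that the bead calibration
#' (fit on brightfield-type areas) can be applied to every event.
#'
#' @param events Data frame with columns \code{cd71_area} and \code{bf_area}
#'   (the latter may contain \code{NA} for events to impute).
#' @return List with \code{slope}, \code{intercept}, \code{r} (Pearson, fit
#'   events), \code{n}, and \code{events}: the input with \code{bf_area}
#'   filled in and a logical \code{bf_area_imputed} column.
#' @export
map_cd71_to_bf_area <- function(events) {
  if (!all(c("cd71_area", "bf_area") %in% names(events)))
    stopf("'events' must have 'cd71_area' and 'bf_area' columns")
  both <- is.finite(events$cd71_area) & is.finite(events$bf_area)
  if (sum(both) < 50L)
    stopf("need >= 50 events with both areas, got %d", sum(both))
  if (stats::sd(events$cd71_area[both]) == 0)
    stopf("degenerate fit: cd71_area is constant")
  fit <- stats::lm(bf_area ~ cd71_area, data = events[both, ])
  cf <- unname(stats::coef(fit))
  r <- stats::cor(events$cd71_area[both], events$bf_area[both])
  ev <- events
  miss <- !is.finite(ev$bf_area) & is.finite(ev$cd71_area)
  ev$bf_area[miss] <- cf[1] + cf[2] * ev$cd71_area[miss]
  ev$bf_area_imputed <- miss
  list(slope = cf[2], intercept = cf[1], r = r, n = sum(both), events = ev)
}

#' Gate enucleated reticulocytes on Draq5
#'
#' Erythroblasts and enucleated reticulocytes separate into two clearly
#' distinct populations on nuclear-dye signal.  This gate splits log total
#' Draq5 intensity by 1D two-means clustering (deterministically initialized
#' at the 25th/75th percentiles); the threshold is the midpoint of the two
#' cluster centers and events below it are called enucleated.  A separation
#' score (center distance over pooled within-cluster SD) below
#' \code{separation_floor} marks the gate unreliable: labels are still
#' returned, with a warning and \code{bimodal = FALSE}.
#'
#' Because the split operates on the log scale with quantile-based
#' initialization, labels are invariant to global multiplicative gain.
#'
#' @param events Data frame with a positive \code{draq5_total} column.
#' @param min_events Minimum number of events (default 100).
#' @param separation_floor Minimum separation score for a reliable gate.
#' @return Object of class \code{"gate_result"}: \code{enucleated} (logical
#'   per event), \code{threshold} (a.u.), \code{log_threshold},
#'   \code{centers} (a.u.), \code{separation}, \code{bimodal}.
#' @export
gate_reticulocytes <- function(events, min_events = 100L, separation_floor = 4) {
  if (!"draq5_total" %in% names(events))
    stopf("'events' must have a 'draq5_total' column")
  x <- events$draq5_total
  if (length(x) < min_events)
    stopf("need >= %d events, got %d", min_events, length(x))
  if (any(x <= 0)) stopf("'draq5_total' must be positive for the log gate")
  lx <- log(x)
  q <- stats::quantile(lx, c(0.25, 0.75), names = FALSE)
  if (diff(q) < .Machine$double.eps^0.5) {
    warnf("Draq5 totals nearly constant: gate unreliable")
    return(structure(list(enucleated = rep(FALSE, length(x)),
                          threshold = exp(mean(lx)), log_threshold = mean(lx),
                          centers = exp(c(q[1], q[2])), separation = 0,
                          bimodal = FALSE),
                     class = "gate_result"))
  }
  km <- stats::kmeans(lx, centers = matrix(q, ncol = 1))
  ctr <- sort(as.numeric(km$centers))
  pooled_sd <- sqrt(km$tot.withinss / max(length(x) - 2, 1))
  separation <- if (pooled_sd > 0) diff(ctr) / pooled_sd else Inf
  log_thr <- mean(ctr)
  bimodal <- separation >= separation_floor
  if (!bimodal)
    warnf("Draq5 gate separation %.2f below floor %.2f: labels unreliable",
          separation, separation_floor)
  structure(list(enucleated = lx < log_thr, threshold = exp(log_thr),
                 log_threshold = log_thr, centers = exp(ctr),
                 separation = separation, bimodal = bimodal),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("Reticulocyte gate on log total Draq5: threshold %.3g a.u.\n",
              x$threshold))
  cat(sprintf("  %d/%d enucleated; separation %.2f (%s)\n",
              sum(x$enucleated), length(x$enucleated), x$separation,
              if (x$bimodal) "bimodal" else "NOT bimodal - unreliable"))
  invisible(x)
}
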