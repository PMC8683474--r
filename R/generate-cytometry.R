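#' Bead acquisition specification
#'
#' Describes a synthetic imaging-flow-cytometry bead acquisition: polystyrene
#' calibration beads of known diameter imaged as area clusters.  The default
#' diameters are the six standard Spherotech sizes used for size calibration
#' of the cytometer.
#'
#' The measured area model is \eqn{A = \pi (d/2 + \mathrm{rim})^2 /
#' \mathrm{px}^2} pixels-squared, i.e. the segmentation mask systematically
#' dilates each object by a rim of constant physical width, multiplied by
#' lognormal noise of coefficient of variation \code{area_cv}.  A fraction
#' \code{outlier_frac} of events is replaced by gross outliers (doublets,
#' debris) with areas 5--10 times the cluster mean.
#'
#' @param diameters Bead diameters in micrometers; strictly positive, distinct.
#' @param n_per_bead Events generated per bead size.
#' @param area_cv Coefficient of variation of the multiplicative area noise.
#' @param outlier_frac Fraction of events replaced by gross outliers
#'   (\code{0 <= outlier_frac < 0.5}).
#' @param rim_bias Systematic mask-dilation rim width in micrometers.
#' @param pixel_size Micrometers per pixel.
#' @return An object of class \code{"bead_spec"}.
#' @seealso [gen_bead_events()], [fit_bead_calibration()]
#' @export
bead_spec <- function(diameters = c(2.0, 3.4, 5.1, 7.4, 9.96, 14.3),
                      n_per_bead = 1000L,
                      area_cv = 0.05,
                      outlier_frac = 0.01,
                      rim_bias = 0.5,
                      pixel_size = 0.5) {
  if (!is.numeric(diameters) || length(diameters) < 1L || any(diameters <= 0))
    stopf("bead diameters must be positive")
  if (anyDuplicated(diameters))
    stopf("bead diameters must be distinct")
  check_scalar_num(n_per_bead, "n_per_bead", positive = TRUE)
  check_scalar_num(area_cv, "area_cv")
  if (area_cv < 0) stopf("'area_cv' must be >= 0")
  check_scalar_num(outlier_frac, "outlier_frac")
  if (outlier_frac < 0 || outlier_frac >= 0.5)
    stopf("'outlier_frac' must be in [0, 0.5)")
  check_scalar_num(rim_bias, "rim_bias")
  check_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  structure(list(diameters = sort(diameters), n_per_bead = as.integer(n_per_bead),
                 area_cv = area_cv, outlier_frac = outlier_frac,
                 rim_bias = rim_bias, pixel_size = pixel_size),
            class = "bead_spec")
}

#' Generate synthetic bead events
#'
#' Simulates one area cluster per bead diameter under the model described in
#' [bead_spec()].  The returned table carries ground-truth columns
#' (\code{true_diameter}, \code{true_outlier}) so that the outlier filter and
#' the calibration fit can be scored by parameter recovery.
#'
#' @param spec A [bead_spec()].
#' @param seed Integer seed; the output is bit-identical for equal
#'   \code{(spec, seed)}.
#' @return A data frame with one row per event: \code{bead_id},
#'   \code{true_diameter} (um), \code{area} (px^2), \code{true_outlier}.
#' @export
gen_bead_events <- function(spec = bead_spec(), seed = 1L) {
  stopifnot(inherits(spec, "bead_spec"))
  set.seed(seed)
  out <- lapply(seq_along(spec$diameters), function(i) {
    d <- spec$diameters[i]
    n <- spec$n_per_bead
    base_area <- pi * (d / 2 + spec$rim_bias)^2 / spec$pixel_size^2
    area <- base_area * lnorm_mult(n, spec$area_cv)
    is_out <- rep(FALSE, n)
    n_out <- round(spec$outlier_frac * n)
    if (n_out > 0) {
      idx <- sample.int(n, n_out)
      area[idx] <- stats::runif(n_out, 5, 10) * base_area
      is_out[idx] <- TRUE
    }
    data.frame(bead_id = i, true_diameter = d, area = area,
               true_outlier = is_out)
  })
  do.call(rbind, out)
}

#' Erythroblast stage specification
#'
#' Per-stage distribution parameters for the synthetic erythroid event
#' generator: population share, cell diameter (lognormal), nuclear offset
#' (truncated normal on \code{[0, 0.45]}), and median channel intensities for
#' the markers carried on the event table.
#'
#' @param name Stage label.
#' @param fraction Population share; fractions over all stages must sum to 1.
#' @param mean_diameter Median cell diameter, micrometers.
#' @param diameter_cv Diameter coefficient of variation.
#' @param mean_offset Mean nuclear offset, in \code{[0, 0.5]}.
#' @param offset_sd Nuclear-offset standard deviation.
#' @param nucleated Logical; enucleated stages (reticulocytes) receive
#'   background-level Draq5 totals.
#' @param marker_means Named numeric vector of median intensities for
#'   \code{ter119, cd71, hcd4, gfp, fsc, draq5} (arbitrary units).
#' @return An object of class \code{"stage_spec"}.
#' @export
stage_spec <- function(name, fraction, mean_diameter, diameter_cv = 0.08,
                       mean_offset = 0.1, offset_sd = 0.03, nucleated = TRUE,
                       marker_means = c(ter119 = 500, cd71 = 2000, hcd4 = 1000,
                                        gfp = 1000, fsc = 50000, draq5 = 5000)) {
  stopifnot(is.character(name), length(name) == 1L)
  check_scalar_num(fraction, "fraction", positive = TRUE)
  check_scalar_num(mean_diameter, "mean_diameter", positive = TRUE)
  if (mean_offset < 0 || mean_offset > 0.5)
    stopf("'mean_offset' must be in [0, 0.5]")
  structure(list(name = name, fraction = fraction,
                 mean_diameter = mean_diameter, diameter_cv = diameter_cv,
                 mean_offset = mean_offset, offset_sd = offset_sd,
                 nucleated = isTRUE(nucleated), marker_means = marker_means),
            class = "stage_spec")
}

#' Default erythroid stage panel
#'
#' Five maturational stages spanning erythroid terminal differentiation, from
#' proerythroblasts to enucleated reticulocytes.  Diameters shrink and the
#' nuclear offset rises with maturation; Ter119 rises while CD71 falls late.
#' The late-erythroblast and reticulocyte diameters (6.7 and 5.6 um) match
#' values typical of cultured fetal-liver erythroblasts.
#'
#' @return A list of [stage_spec()] objects.
#' @export
erythroid_stage_defaults <- function() {
  list(
    stage_spec("ProE",  0.15, 10.5, 0.08, 0.06, 0.02, TRUE,
               c(ter119 = 200, cd71 = 3000, hcd4 = 1000, gfp = 1000,
                 fsc = 90000, draq5 = 9000)),
    stage_spec("EryA",  0.25,  9.0, 0.08, 0.12, 0.03, TRUE,
               c(ter119 = 800, cd71 = 3000, hcd4 = 1000, gfp = 1000,
                 fsc = 70000, draq5 = 8000)),
    stage_spec("EryB",  0.25,  7.5, 0.08, 0.20, 0.04, TRUE,
               c(ter119 = 1500, cd71 = 2500, hcd4 = 1000, gfp = 1000,
                 fsc = 50000, draq5 = 6000)),
    stage_spec("EryC",  0.20,  6.7, 0.10, 0.30, 0.05, TRUE,
               c(ter119 = 2000, cd71 = 800, hcd4 = 1000, gfp = 1000,
                 fsc = 30000, draq5 = 5000)),
    stage_spec("Retic", 0.15,  5.6, 0.09, 0.00, 0.00, FALSE,
               c(ter119 = 2000, cd71 = 600, hcd4 = 1000, gfp = 1000,
                 fsc = 20000, draq5 = 50))
  )
}

#' Generate a synthetic erythroid event table
#'
#' Draws per-event maturational stages by the stage fractions, then samples
#' diameter, nuclear offset, mask areas, centroids and channel intensities
#' stage-wise.  Centroid coordinates are laid out so that the Euclidean
#' distance between cell and nucleus centroids (the delta centroid) equals
#' \code{offset * diameter}, consistent with the mask geometry used by the
#' morphometry module.  Enucleated stages receive background Draq5 totals.
#'
#' @param stages List of [stage_spec()]; fractions must sum to 1.
#' @param n Number of events.
#' @param seed Integer seed.
#' @param sample_id Sample label stored on every row.
#' @param pixel_size Micrometers per pixel used to convert areas to px^2.
#' @param marker_cv Lognormal CV for the marker channels.
#' @return A data frame (one row per event) with measurement columns
#'   \code{bf_area, cd71_area, cell_centroid_x/y, nuc_centroid_x/y,
#'   draq5_mean, draq5_total, ter119, cd71, hcd4, gfp, fsc} and truth columns
#'   \code{true_stage, true_diameter, true_offset, true_nucleated}.
#' @export
gen_erythroid_events <- function(stages = erythroid_stage_defaults(), n = 10000L,
                                 seed = 1L, sample_id = "sample1",
                                 pixel_size = 0.5, marker_cv = 0.35) {
  if (length(n) != 1L || n <= 0) stopf("'n' must be a positive integer")
  fr <- vapply(stages, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8)
    stopf("stage fractions must sum to 1 (got %g)", sum(fr))
  set.seed(seed)
  n <- as.integer(n)
  k <- length(stages)
  idx <- sample.int(k, n, replace = TRUE, prob = fr)

  diam <- numeric(n); off <- numeric(n)
  nucleated <- logical(n); stage_name <- character(n)
  markers <- matrix(0, n, 6,
                    dimnames = list(NULL, c("ter119", "cd71", "hcd4", "gfp",
                                            "fsc", "draq5")))
  for (i in seq_len(k)) {
    sel <- idx == i
    m <- sum(sel)
    if (m == 0) next
    st <- stages[[i]]
    stage_name[sel] <- st$name
    nucleated[sel] <- st$nucleated
    diam[sel] <- st$mean_diameter * lnorm_mult(m, st$diameter_cv)
    o <- stats::rnorm(m, st$mean_offset, st$offset_sd)
    off[sel] <- pmin(pmax(o, 0), 0.45)
    for (ch in colnames(markers))
      markers[sel, ch] <- stats::rlnorm(m, log(st$marker_means[[ch]]),
                                        sqrt(log1p(marker_cv^2)))
  }

  bf_area <- pi * diam^2 / 4 / pixel_size^2 * lnorm_mult(n, 0.03)
  cd71_area <- bf_area * 1.05 * lnorm_mult(n, 0.04)
  cx <- stats::runif(n, 20, 80)
  cy <- stats::runif(n, 20, 80)
  delta_px <- off * diam / pixel_size
  ang <- stats::runif(n, 0, 2 * pi)
  nuc_area_um2 <- pi * (0.75 * diam)^2 / 4   # nuclei ~75% of cell diameter
  draq5_total <- markers[, "draq5"]
  draq5_mean <- ifelse(nucleated, draq5_total / (nuc_area_um2 / pixel_size^2),
                       draq5_total / (pi * diam^2 / 4 / pixel_size^2))

  data.frame(
    sample_id = sample_id,
    bf_area = bf_area, cd71_area = cd71_area,
    cell_centroid_x = cx, cell_centroid_y = cy,
    nuc_centroid_x = cx + delta_px * cos(ang),
    nuc_centroid_y = cy + delta_px * sin(ang),
    draq5_mean = draq5_mean, draq5_total = draq5_total,
    ter119 = markers[, "ter119"], cd71 = markers[, "cd71"],
    hcd4 = markers[, "hcd4"], gfp = markers[, "gfp"], fsc = markers[, "fsc"],
    true_stage = stage_name, true_diameter = diam, true_offset = off,
    true_nucleated = nucleated
  )
}

#' Rasterize a synthetic cell/nucleus image pair
#'
#' Draws a cell disc and an interior nucleus disc on a common pixel grid; the
#' nucleus center is displaced from the cell center by \code{offset *
#' diameter} micrometers, the defining geometry of the nuclear-offset
#' statistic.  Intensity images are uniform within each mask, with optional
#' additive Gaussian noise.  Subpixel placement of the cell center is
#' randomized so that rasterization error is exercised.
#'
#' @param diameter Cell diameter, micrometers.
#' @param nuc_diameter Nucleus diameter, micrometers; must fit inside the cell
#'   at the requested offset.
#' @param offset Nuclear offset (unitless, \code{>= 0}).
#' @param pixel_size Micrometers per pixel.
#' @param seed Integer seed (subpixel jitter, displacement angle, noise).
#' @param noise_sd Additive Gaussian noise SD on intensities inside the masks.
#' @return A list with integer label matrices \code{cell_mask},
#'   \code{nuc_mask}, intensity matrices \code{cell_img}, \code{nuc_img},
#'   \code{pixel_size}, and a \code{truth} list holding exact continuous
#'   centroids (um), areas (um^2), \code{delta_centroid} and \code{offset}.
#' @export
gen_image_pair <- function(diameter, nuc_diameter, offset, pixel_size = 0.25,
                           seed = 1L, noise_sd = 0) {
  check_scalar_num(diameter, "diameter", positive = TRUE)
  check_scalar_num(nuc_diameter, "nuc_diameter", positive = TRUE)
  check_scalar_num(offset, "offset")
  if (offset < 0) stopf("'offset' must be >= 0")
  if (nuc_diameter >= diameter)
    stopf("nucleus diameter must be smaller than cell diameter")
  if (offset * diameter + nuc_diameter / 2 > diameter / 2 + 1e-12)
    stopf("nucleus escapes the cell boundary: offset*diameter + nuc_r > cell_r")
  set.seed(seed)

  margin <- 2 * pixel_size + diameter * 0.1
  side <- diameter + 2 * margin
  npx <- ceiling(side / pixel_size)
  ctr <- npx * pixel_size / 2
  # subpixel jitter of the scene within the grid
  cx <- ctr + stats::runif(1, -0.5, 0.5) * pixel_size
  cy <- ctr + stats::runif(1, -0.5, 0.5) * pixel_size
  ang <- stats::runif(1, 0, 2 * pi)
  nx <- cx + offset * diameter * cos(ang)
  ny <- cy + offset * diameter * sin(ang)

  px <- (seq_len(npx) - 0.5) * pixel_size
  X <- matrix(px, npx, npx, byrow = TRUE)   # x along columns
  Y <- matrix(px, npx, npx)                 # y along rows
  cell_mask <- ((X - cx)^2 + (Y - cy)^2 <= (diameter / 2)^2) * 1L
  nuc_mask <- ((X - nx)^2 + (Y - ny)^2 <= (nuc_diameter / 2)^2) * 1L

  cell_img <- cell_mask * 1.0
  nuc_img <- nuc_mask * 1.0
  if (noise_sd > 0) {
    cell_img <- pmax(cell_img + cell_mask * stats::rnorm(npx^2, 0, noise_sd), 0)
    nuc_img <- pmax(nuc_img + nuc_mask * stats::rnorm(npx^2, 0, noise_sd), 0)
  }

  list(cell_mask = cell_mask, nuc_mask = nuc_mask,
       cell_img = cell_img, nuc_img = nuc_img, pixel_size = pixel_size,
       truth = list(cell_centroid = c(x = cx, y = cy),
                    nuc_centroid = c(x = nx, y = ny),
                    cell_area = pi * diameter^2 / 4,
                    nuc_area = pi * nuc_diameter^2 / 4,
                    cell_diameter = diameter, nuc_diameter = nuc_diameter,
                    delta_centroid = offset * diameter, offset = offset))
}
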