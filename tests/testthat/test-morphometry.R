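test_that("outlier filter removes the Gaussian tail fraction and respects edge cases", {
  expect_equal(filter_outliers(rep(5, 20))$removed_fraction, 0)
  expect_error(filter_outliers(rep(5, 20), k = 0), "undefined")
  set.seed(1)
  f <- filter_outliers(rnorm(1e5), k = 3)
  expect_equal(f$removed_fraction, 2 * pnorm(-3), tolerance = 0.3)
  # log-scale filtering of lognormal data behaves like Gaussian filtering
  fl <- filter_outliers(exp(rnorm(1e5)), k = 3, log_scale = TRUE)
  expect_equal(fl$removed_fraction, 2 * pnorm(-3), tolerance = 0.3)
  expect_error(filter_outliers(c(-1, 2), log_scale = TRUE), "positive")
})

test_that("bead calibration is exact on noiseless discs and round-trips", {
  sp <- bead_spec(area_cv = 0, outlier_frac = 0, rim_bias = 0, pixel_size = 1,
                  n_per_bead = 20)
  cal <- fit_bead_calibration(gen_bead_events(sp, 1))
  expect_equal(cal$c0, 0, tolerance = 1e-8)
  expect_equal(cal$c1, 0, tolerance = 1e-8)
  expect_equal(cal$c2, pi / 4, tolerance = 1e-8)
  expect_equal(cal$r2, 1)
  expect_equal(as.numeric(area_to_diameter(cal, 25 * pi / 4)), 5, tolerance = 1e-9)

  cal2 <- fit_bead_calibration(gen_bead_events(bead_spec(), 7))
  d_in <- seq(cal2$domain[1], cal2$domain[2], length.out = 50)
  d_out <- area_to_diameter(cal2, bead_area(cal2, d_in))
  expect_equal(as.numeric(d_out), d_in, tolerance = 1e-9)

  expect_error(fit_bead_calibration(
    gen_bead_events(bead_spec(diameters = c(2, 5), n_per_bead = 50), 1)),
    "3 distinct")
})

test_that("calibration absorbs rim bias: inverse-predicted bead diameters within 2%", {
  ev <- gen_bead_events(bead_spec(), 11)   # 5% CV, 1% outliers, 0.5 um rim
  cal <- fit_bead_calibration(ev)
  clean <- ev[!ev$true_outlier, ]
  med <- tapply(clean$area, clean$true_diameter, median)
  d_hat <- suppressWarnings(area_to_diameter(cal, as.numeric(med)))
  truth <- as.numeric(names(med))
  expect_lt(max(abs(d_hat - truth) / truth), 0.02)
  expect_gt(cal$r2, 0.97)
})

test_that("area_to_diameter flags extrapolation and rejects impossible areas", {
  cal <- fit_bead_calibration(gen_bead_events(bead_spec(), 3))
  expect_warning(d <- area_to_diameter(cal, max(cal$area_range) * 4),
                 "extrapolat")
  expect_true(attr(d, "extrapolated"))
  low <- cal$c0 - cal$c1^2 / (4 * cal$c2) - 10   # below the parabola minimum
  expect_error(area_to_diameter(cal, low), "discriminant")
})

test_that("mask features recover the rasterized geometry", {
  p0 <- gen_image_pair(10, 6, 0, 0.25, seed = 1)
  f0 <- mask_features(p0$cell_mask, p0$nuc_mask, pixel_size = 0.25)
  expect_lt(f0$delta_centroid, 0.25)      # concentric up to rasterization
  expect_lt(f0$nuclear_offset, 0.025)

  p <- gen_image_pair(10, 6, 0.2, 0.25, seed = 5)
  f <- mask_features(p$cell_mask, p$nuc_mask, p$cell_img, p$nuc_img, 0.25)
  expect_equal(f$nuclear_offset, 0.2, tolerance = 0.25 / 10)
  expect_equal(f$cell_diameter, 10, tolerance = 0.05)
  expect_equal(f$cell_area, pi * 25, tolerance = 0.5)
})

test_that("offset recovery stays within a pixel across random scenes", {
  errs <- vapply(1:40, function(i) {
    set.seed(i)
    d <- runif(1, 8, 12)
    off <- runif(1, 0, 0.2)
    p <- gen_image_pair(d, runif(1, 0.3, 0.5) * d, off, 0.25, seed = i)
    f <- mask_features(p$cell_mask, p$nuc_mask, pixel_size = 0.25)
    abs(f$delta_centroid - p$truth$delta_centroid)
  }, numeric(1))
  expect_lt(max(errs), 0.25)
})

test_that("mask features are invariant to rigid motion and intensity gain", {
  p <- gen_image_pair(8, 4, 0.15, 0.25, seed = 9)
  f <- mask_features(p$cell_mask, p$nuc_mask, p$cell_img, p$nuc_img, 0.25)

  rot90 <- function(m) t(m)[, nrow(m):1]   # 90-degree rotation
  fr <- mask_features(rot90(p$cell_mask), rot90(p$nuc_mask),
                      rot90(p$cell_img), rot90(p$nuc_img), 0.25)
  pad <- function(m, k = 6) {              # translation by k pixels
    out <- matrix(0, nrow(m) + k, ncol(m) + k)
    out[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m))] <- m
    out
  }
  ft <- mask_features(pad(p$cell_mask), pad(p$nuc_mask),
                      pad(p$cell_img), pad(p$nuc_img), 0.25)
  fg <- mask_features(p$cell_mask, p$nuc_mask, 7 * p$cell_img, 3 * p$nuc_img, 0.25)
  for (other in list(fr, ft, fg)) {
    expect_equal(other$delta_centroid, f$delta_centroid, tolerance = 1e-9)
    expect_equal(other$nuclear_offset, f$nuclear_offset, tolerance = 1e-9)
    expect_equal(other$cell_area, f$cell_area)
  }
  expect_error(mask_features(p$cell_mask, p$nuc_mask[1:5, 1:5], pixel_size = 0.25),
               "shape")
  expect_error(mask_features(p$cell_mask * 0, p$nuc_mask, pixel_size = 0.25),
               "empty")
})

test_that("nuclear offset is stable under finer rasterization", {
  f1 <- mask_features_from_pair(gen_image_pair(10, 5, 0.2, 0.5, seed = 3))
  f2 <- mask_features_from_pair(gen_image_pair(10, 5, 0.2, 0.125, seed = 3))
  expect_equal(f1$nuclear_offset, 0.2, tolerance = 0.5 / 10)
  expect_equal(f2$nuclear_offset, 0.2, tolerance = 0.125 / 10)
})

test_that("CD71-to-brightfield area mapping fits, imputes and composes", {
  set.seed(2)
  n <- 2000
  cd71 <- runif(n, 100, 800)
  bf <- 1.2 * cd71 + 50
  ev <- data.frame(cd71_area = cd71, bf_area = bf)
  m0 <- map_cd71_to_bf_area(ev)
  expect_equal(m0$slope, 1.2, tolerance = 1e-9)
  expect_equal(m0$intercept, 50, tolerance = 1e-6)

  evn <- ev
  evn$bf_area <- bf * (1 + rnorm(n, 0, 0.02))
  evn$bf_area[1:200] <- NA
  m <- map_cd71_to_bf_area(evn)
  expect_true(m$slope > 1.18 && m$slope < 1.22)
  expect_true(all(is.finite(m$events$bf_area)))
  expect_true(all(m$events$bf_area_imputed[1:200]))
  expect_error(map_cd71_to_bf_area(data.frame(cd71_area = rep(1, 100),
                                              bf_area = rep(2, 100))),
               "degenerate|constant")

  # composition: imputed areas -> calibrated diameters within 3% of truth
  st <- list(stage_spec("a", 0.5, 7.5), stage_spec("b", 0.5, 6.7))
  er <- gen_erythroid_events(st, 2e4, 3, pixel_size = 0.5)
  er$bf_area[seq(1, nrow(er), by = 4)] <- NA
  mm <- map_cd71_to_bf_area(er)
  cal <- fit_bead_calibration(gen_bead_events(bead_spec(rim_bias = 0, pixel_size = 0.5), 2))
  dd <- suppressWarnings(area_to_diameter(cal, mm$events$bf_area))
  med <- tapply(as.numeric(dd), er$true_stage, median)
  expect_equal(as.numeric(med[c("a", "b")]), c(7.5, 6.7), tolerance = 0.03)
})

test_that("reticulocyte gate separates Draq5 modes and is gain-invariant", {
  ev <- gen_erythroid_events(two_stage_retic(0.3), 5000, 2)
  g <- gate_reticulocytes(ev)
  expect_true(g$bimodal)
  expect_gte(mean(g$enucleated == !ev$true_nucleated), 0.99)
  expect_true(g$threshold > g$centers[1] && g$threshold < g$centers[2])

  ev2 <- ev
  ev2$draq5_total <- ev2$draq5_total * 2
  expect_identical(gate_reticulocytes(ev2)$enucleated, g$enucleated)

  allnuc <- gen_erythroid_events(list(stage_spec("ery", 1, 8)), 1000, 4)
  expect_warning(gn <- gate_reticulocytes(allnuc), "unreliable")
  expect_false(gn$bimodal)
  expect_error(gate_reticulocytes(ev[1:50, ]), ">= 100")
})

test_that("quintile staging holds 20% reference bins and transfers edges", {
  qs <- quintile_stage(as.numeric(1:100), list(ref = as.numeric(1:100)))
  expect_equal(qs$summary$n, rep(20L, 5))
  # tie rule: a value equal to an edge lands in the lower bin
  expect_equal(unname(qs$assignments$ref[c(20, 21)]), c(1L, 2L))

  # Epo-shifted sample: same offsets, larger diameters -> larger per-bin
  # medians in every bin, with the largest gap in the mature bins
  set.seed(7)
  n <- 20000
  off_sal <- rbeta(n, 2, 5) * 0.45
  off_epo <- rbeta(n, 2, 5) * 0.45
  diam_sal <- 9 - 6 * off_sal + rnorm(n, 0, 0.2)
  diam_epo <- 9 - 6 * off_epo + rnorm(n, 0, 0.2) + 0.3 + 1.5 * off_epo
  qs2 <- quintile_stage(off_sal,
                        queries = list(saline = off_sal, epo = off_epo),
                        feature = list(saline = diam_sal, epo = diam_epo))
  s <- qs2$summary
  gap <- s$median_feature[s$sample == "epo"] - s$median_feature[s$sample == "saline"]
  expect_true(all(gap > 0))
  expect_gt(mean(gap[4:5]), mean(gap[1:2]))
  # reference bins hold 20% up to ties
  expect_equal(s$n[s$sample == "saline"], rep(n / 5, 5), tolerance = 0.01)
  expect_warning(quintile_stage(off_sal, list(a = numeric(0), b = off_epo)),
                 "empty")
  expect_error(quintile_stage(rep(1, 100), list(a = 1)), "increasing")
})

test_that("composite quantile ratios are 1 for identical samples and track construction", {
  set.seed(3)
  n <- 3000
  mk <- function() data.frame(hcd4 = runif(n), gfp = runif(n),
                              diameter = rnorm(n, 8, 0.5))
  s <- mk()
  r <- composite_quantile_ratio(list(a = s, b = s, ref = s), reference = "ref")
  expect_true(all(abs(unlist(r$ratios) - 1) < 1e-12, na.rm = TRUE))

  # diameter depends only on the chB (gfp) bin -> ratios constant along chA
  gfp <- runif(n)
  s2 <- data.frame(hcd4 = runif(n), gfp = gfp, diameter = 6 + 2 * floor(gfp * 5) / 5)
  s3 <- data.frame(hcd4 = runif(n), gfp = runif(n),
                   diameter = 6 + 2 * floor(runif(n) * 5) / 5)
  r2 <- composite_quantile_ratio(list(q = s2, ref = s3), reference = "ref")
  m <- r2$means$q   # per-bin mean diameter of the constructed sample
  expect_lt(max(apply(m, 2, function(col) diff(range(col, na.rm = TRUE)))), 0.05)

  # pooled edges split pooled events into k equal shares per channel
  pooled <- c(s2$gfp, s3$gfp)
  shares <- table(findInterval(pooled, r2$edges_b, left.open = TRUE))
  expect_equal(as.numeric(shares) / length(pooled), rep(0.2, 5), tolerance = 0.01)
  expect_error(composite_quantile_ratio(list(a = s), reference = "zz"), "absent")
})

test_that("expression-size response finds monotone dose-response and rejects nulls", {
  set.seed(4)
  e <- runif(3000, 1, 100)
  r <- expression_size_response(e, 5 + 0.02 * e, n_bins = 6)
  expect_equal(r$rho, 1)
  expect_lt(r$p, 0.01)

  null_ps <- vapply(1:20, function(i) {
    set.seed(100 + i)
    expression_size_response(runif(2000), rnorm(2000, 8), n_bins = 6)$p
  }, numeric(1))
  expect_gte(mean(null_ps > 0.05), 0.8)
  expect_error(expression_size_response(rep(1, 1000), rnorm(1000)), "constant")
})
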