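test_that("baseline correction subtracts the subject baseline mean", {
  pan <- data.frame(
    subject_id = "A", group = "treated",
    time_days = c(-21, -14, -7, 7), analyte = "mcv",
    value = c(88, 90, 92, 95))
  bc <- baseline_correct(pan)
  expect_equal(bc$corrected[4], 5)
  expect_equal(bc$baseline_mean, rep(90, 4))
  expect_true(all(bc$is_baseline[1:3]))

  nob <- pan[pan$time_days > 0, ]
  expect_error(baseline_correct(nob), "lacking baseline")

  quiet <- cohort_design(analyte_baselines = data.frame(
    analyte = "mcv", mean = 90, between_sd = 3, within_sd = 0))
  p0 <- gen_cbc_panel(quiet, seed = 1)
  bc0 <- baseline_correct(p0[p0$group == "placebo", ])
  expect_true(all(abs(bc0$corrected) < 1e-12))

  # generator-truth recovery: +4 fL MCV effect at end of treatment
  pan2 <- gen_cbc_panel(seed = 6)
  bc2 <- baseline_correct(pan2[pan2$analyte == "mcv", ])
  eow <- bc2$group == "treated" & bc2$time_days == 21
  expect_equal(mean(bc2$corrected[eow]), 4, tolerance = 0.15)
})

test_that("fractional change matches hand arithmetic and generator truth", {
  pan <- data.frame(subject_id = "A", group = "treated",
                    time_days = c(-7, 7), analyte = "mcv", value = c(90, 95))
  fc <- fractional_change(pan)
  expect_equal(fc$frac_change[2], 5 / 90)
  expect_equal(fc$frac_change[1], 0)

  z <- pan; z$value <- c(0, 5)
  expect_error(fractional_change(z), "zero baseline")

  hb <- gen_cbc_panel(seed = 2)
  hb <- fractional_change(hb[hb$analyte == "hemoglobin", ])
  inw <- hb$group == "treated" & hb$time_days >= 7 & hb$time_days <= 21
  expect_lt(abs(mean(hb$frac_change[inw]) - 0.05), 0.01)
})

test_that("correlations behave on perfect, null and trending panels", {
  t_days <- c(-7, 0, 7, 14)
  mk_panel <- function(xa, ya) {
    rbind(data.frame(subject_id = rep(c("A", "B"), each = 4), group = "treated",
                     time_days = rep(t_days, 2), analyte = "x", value = xa),
          data.frame(subject_id = rep(c("A", "B"), each = 4), group = "treated",
                     time_days = rep(t_days, 2), analyte = "y", value = ya))
  }
  x <- c(1, 2, 3, 4, 2, 3, 4, 5)
  expect_equal(correlate(mk_panel(x, x), "x", "y")$r, 1)

  # independent analytes: |r| < 0.1 in most seeded runs
  nulls <- vapply(1:20, function(i) {
    set.seed(i)
    pan <- rbind(
      data.frame(subject_id = rep(sprintf("S%02d", 1:50), each = 10),
                 group = "treated", time_days = rep(1:10, 50),
                 analyte = "x", value = rnorm(500)),
      data.frame(subject_id = rep(sprintf("S%02d", 1:50), each = 10),
                 group = "treated", time_days = rep(1:10, 50),
                 analyte = "y", value = rnorm(500)))
    abs(correlate(pan, "x", "y")$r)
  }, numeric(1))
  expect_gte(mean(nulls < 0.1), 0.9)

  # shared latent time trend in MCV and RDW -> strong pooled correlation
  strong <- cohort_design(analyte_baselines = data.frame(
    analyte = c("mcv", "rdw_sd"), mean = c(90, 42),
    between_sd = c(0.5, 0.5), within_sd = c(0.4, 0.4)))
  pan <- gen_cbc_panel(strong, seed = 3)
  expect_gt(correlate(pan, "mcv", "rdw_sd")$r, 0.4)

  ps <- correlate(pan, "mcv", "rdw_sd", scope = "per_subject")
  expect_gt(ps$r, 0.4)
  expect_error(correlate(pan[1:4, ], "mcv", "rdw_sd"), "pairs")
})

test_that("summary-statistics Welch test matches full-data t.test and known values", {
  w0 <- welch_t_summary(5, 1, 10, 5, 2, 12)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p, 1)

  # printed colony-area summaries: t ~ 8.24, df ~ 110, p of order 1e-13
  w <- welch_t_summary(439, 208, 75, 217, 106, 75)
  expect_equal(w$statistic, 8.2354, tolerance = 1e-4)
  expect_equal(w$df, 110, tolerance = 0.01)
  expect_lt(w$p, 1e-12)
  expect_gt(w$p, 1e-14)

  # doubling both n at fixed m, s scales |t| by sqrt(2)
  w2 <- welch_t_summary(439, 208, 150, 217, 106, 150)
  expect_equal(w2$statistic / w$statistic, sqrt(2), tolerance = 1e-9)

  # exact agreement with stats::t.test when summaries come from real samples
  set.seed(9)
  a <- rnorm(20, 1); b <- rnorm(15, 0, 2)
  ref <- t.test(a, b)
  ws <- welch_t_summary(mean(a), sd(a), 20, mean(b), sd(b), 15)
  expect_equal(ws$statistic, unname(ref$statistic))
  expect_equal(ws$df, unname(ref$parameter))
  expect_equal(ws$p, ref$p.value)
  expect_equal(ws$ci, as.numeric(ref$conf.int))
  expect_error(welch_t_summary(1, 1, 1, 2, 1, 10), ">= 2")
  expect_error(welch_t_summary(1, 0, 5, 2, 1, 10), "> 0")
})

test_that("paired t test pairs by key and flags degenerate input", {
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "identical")
  expect_error(paired_t(c(1, 2), c(1, 2, 3), c("a", "b"), c("a", "b", "c")),
               "unmatched")
  # keys in different orders pair correctly: pairing by key halves each value
  set.seed(1)
  a <- rnorm(8, 10)
  res <- paired_t(a, rev(a) / 2, keys_a = letters[1:8], keys_b = rev(letters[1:8]))
  ref <- t.test(a - a / 2)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)

  # power at delta = 1 SD, 8 pairs tracks the noncentral-t closed form
  reps <- 400
  hits <- vapply(1:reps, function(i) {
    set.seed(1000 + i)
    d <- rnorm(8, 1, 1)
    paired_t(d, rep(0, 8))$p < 0.05
  }, logical(1))
  ncp <- 1 * sqrt(8)
  crit <- qt(0.975, 7)
  power <- 1 - pt(crit, 7, ncp) + pt(-crit, 7, ncp)
  expect_equal(mean(hits), power, tolerance = 0.05)
})

test_that("BH adjustment follows the step-up rule and is order-equivariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(3)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
  adj <- bh_adjust(p)
  expect_true(!is.unsorted(adj[order(p)]))
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
})

test_that("per-timepoint contrasts detect the effect window and stay calibrated", {
  pan <- gen_cbc_panel(seed = 4)
  ctr <- per_timepoint_contrasts(pan, "mcv")
  expect_true(all(ctr$p_adj[ctr$time_days %in% c(14, 21, 28)] < 0.05))
  expect_gt(ctr$p_adj[ctr$time_days == 0], 0.05)
  expect_equal(nrow(ctr), 9)

  # noiseless identical groups: all p = 1, error-free
  quiet <- cohort_design(analyte_baselines = data.frame(
    analyte = "mcv", mean = 90, between_sd = 0, within_sd = 0),
    treatment_effects = list(mcv = list(type = "additive",
      breaks = data.frame(time_days = c(0, 56), value = c(0, 0)))))
  ctr0 <- per_timepoint_contrasts(gen_cbc_panel(quiet, seed = 1), "mcv")
  expect_true(all(ctr0$p == 1))
})
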