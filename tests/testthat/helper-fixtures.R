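# Shared fixtures built in code.

# two-stage erythroblast mixture with one enucleated stage
two_stage_retic <- function(retic_frac = 0.3) {
  list(
    stage_spec("ery", 1 - retic_frac, 8, mean_offset = 0.15),
    stage_spec("retic", retic_frac, 5.6, nucleated = FALSE,
               marker_means = c(ter119 = 2000, cd71 = 600, hcd4 = 1000,
                                gfp = 1000, fsc = 2e4, draq5 = 50)))
}

# independent oracle for the timer median B/(B+R): level sets of
# g(a) = min(a, tau)/(T + a) integrated against the closed-form age CDF
# F(a) = 2(1 - 2^(-a/T)); no package code involved.
ft_oracle_median <- function(T, tau) {
  Fage <- function(a) 2 * (1 - 2^(-a / T))
  gmax <- tau / (T + tau)
  gT <- tau / (2 * T)
  prob_le <- function(r) {
    a1 <- min(r * T / (1 - r), tau)
    p <- Fage(a1)
    if (r < gT) p
    else if (r < gmax) p + (1 - Fage(tau / r - T))
    else 1
  }
  stats::uniroot(function(r) prob_le(r) - 0.5, c(1e-9, gmax - 1e-9),
                 tol = 1e-10)$root
}

mask_features_from_pair <- function(p) {
  mask_features(p$cell_mask, p$nuc_mask, p$cell_img, p$nuc_img, p$pixel_size)
}

# brute-force discrete-event snapshot occupancy: simulate explicit cells on
# a fine clock, independent of gen_snapshot's internals
snapshot_brute_force <- function(durations, n_cells, seed) {
  set.seed(seed)
  total <- sum(durations)
  horizon <- 5 * total
  arrivals <- sort(stats::runif(n_cells, 0, horizon))
  snap <- horizon - 0.25 * total   # well past burn-in
  age <- snap - arrivals
  present <- age >= 0 & age < total
  stage <- cut(age[present], breaks = c(0, cumsum(durations)),
               labels = FALSE, include.lowest = TRUE)
  tabulate(stage, nbins = length(durations))
}
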