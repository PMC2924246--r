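# shared fixtures and oracles, built in code at test time

# mean of the analytic barrier density over 1-bp or wider bins
# (a lattice/histogram cell holds probability MASS; the continuum density is
# integrated over the matching bin before comparison)
ana_bin_means <- function(starts, width, params) {
  vapply(starts, function(a)
    stats::integrate(function(u) barrier_density(u, params), a, a + width,
                     rel.tol = 1e-9)$value / width, numeric(1))
}

# family-calibrated agreement check between a binned MC histogram and the
# analytic curve: nominal 3-sigma confidence applied family-wise
# (chi-square goodness of fit + Bonferroni per-bin bound); bins with zero
# standard error must agree exactly (depletion layer)
mc_agrees <- function(mc, ana, n_bins = length(ana)) {
  live <- mc$se > 0
  z <- (mc$density[live] - ana[live]) / mc$se[live]
  alpha <- 2 * stats::pnorm(-3)                      # 3-sigma level
  gof_ok <- sum(z^2) < stats::qchisq(1 - alpha, df = sum(live))
  bonf_ok <- max(abs(z)) < stats::qnorm(1 - alpha / (2 * n_bins))
  zero_ok <- all(mc$density[!live] == 0 & ana[!live] < 1e-12)
  list(ok = gof_ok && bonf_ok && zero_ok, max_abs_z = max(abs(z)),
       chi2_ratio = sum(z^2) / sum(live))
}

# build an aligned_profile object from a model curve (for fitting tests)
model_profile <- function(offsets, values, kind = "plus1") {
  prof <- data.frame(offset = offsets, mean_weight = values,
                     n_genes = rep(1L, length(offsets)))
  class(prof) <- c("aligned_profile", "data.frame")
  attr(prof, "anchor_kind") <- kind
  prof
}

# cohort shared by the parameter-recovery and robustness acceptance checks
.acc_cache <- new.env(parent = emptyenv())
acceptance_cohort <- function() {
  if (is.null(.acc_cache$cohort)) {
    sc <- synthetic_config(seed = 101L, n_genes = 2000L)
    .acc_cache$cohort <- simulate_cohort(sc)
  }
  .acc_cache$cohort
}
acceptance_profiles <- function() {
  if (is.null(.acc_cache$profiles)) {
    coh <- acceptance_cohort()
    dens <- reads_to_density(coh$reads, 147,
                             c(chrSim = coh$chrom_length))
    fl <- find_flanking(coh$genes, coh$calls)
    ap <- data.frame(chrom = fl$chrom, strand = fl$strand, anchor = fl$plus1)
    am <- data.frame(chrom = fl$chrom, strand = fl$strand, anchor = fl$minus1)
    .acc_cache$profiles <- list(
      density = dens, flanking = fl,
      plus = align_average(dens, ap, 2000, "plus1"),
      minus = align_average(dens, am, 2000, "minus1"))
  }
  .acc_cache$profiles
}
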