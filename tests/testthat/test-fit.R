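p177 <- tonks_params(147, 177)

noiseless_profile <- function(A = 2, x0 = 0, dbar = 177, window = 2000,
                              spike_at_zero = NULL) {
  off <- seq(-200, window)
  y <- statpos:::tonks_curve(off, A, x0, dbar, 147)
  if (!is.null(spike_at_zero)) y[off == 0] <- spike_at_zero
  model_profile(off, y)
}

# a -1-alignment-style profile (pattern grows toward negative offsets):
# the mirror image of the model curve, as align_average would produce it
noiseless_minus_profile <- function(A = 2, x0 = 0, dbar = 177,
                                    window = 2000) {
  off <- seq(-window, 200)
  y <- statpos:::tonks_curve(-off, A, x0, dbar, 147)
  model_profile(off, y, kind = "minus1")
}

test_that("noiseless self-consistency: exact parameter recovery", {
  prof <- noiseless_profile(A = 2, x0 = 0, dbar = 177)
  cfg <- fit_config(n_starts = 25, seed = 3)
  f <- fit_profile(prof, cfg, basin = "free")
  expect_equal(f$A, 2, tolerance = 1e-6)
  expect_equal(f$x0, 0, tolerance = 1e-4)
  expect_equal(f$dbar, 177, tolerance = 1e-6)
  expect_lt(f$chi2, 1e-18)
  expect_equal(f$scenario, "direct")
  expect_true(f$converged)
})

test_that("a one-width shift lands in the indirect basin", {
  prof <- noiseless_profile(A = 2, x0 = -147, dbar = 177)
  cfg <- fit_config(n_starts = 25, seed = 4)
  f <- fit_profile(prof, cfg, basin = "free")
  expect_equal(f$x0, -147, tolerance = 1e-3)
  expect_equal(f$scenario, "indirect")
  expect_equal(f$dbar, 177, tolerance = 1e-5)
})

test_that("offset-only fit recovers both boundary conditions", {
  cfg <- fit_config(n_starts = 30, seed = 5)
  ind <- noiseless_minus_profile(A = 2, x0 = -147, dbar = 177)
  f1 <- fit_minus_fixed(ind, A_fixed = 2, dbar_fixed = 177, cfg)
  expect_equal(f1$x0, -147, tolerance = 1e-3)
  expect_equal(f1$scenario, "indirect")
  dirp <- noiseless_minus_profile(A = 2, x0 = 0, dbar = 177)
  f2 <- fit_minus_fixed(dirp, A_fixed = 2, dbar_fixed = 177, cfg)
  expect_equal(f2$x0, 0, tolerance = 1e-3)
  expect_equal(f2$scenario, "direct")
})

test_that("convolved fit with a point-mass kernel equals the plain fit", {
  prof <- noiseless_profile(A = 2, x0 = 0, dbar = 177, spike_at_zero = 1)
  cfg <- fit_config(n_starts = 20, seed = 6)
  fc <- fit_convolved(prof, cfg)
  fp <- fit_profile(prof, cfg, basin = "direct")
  expect_equal(fc$A, fp$A, tolerance = 1e-5)
  expect_equal(fc$dbar, fp$dbar, tolerance = 1e-5)
  expect_lt(fc$chi2, 1e-16)
})

test_that("convolution absorbs anchor positional variability", {
  # cohort whose only positional noise is the +1 nucleosome's cell-to-cell
  # variation (sd 15 bp) -- the effect the convolved model is built for
  sc <- synthetic_config(seed = 41, n_genes = 800, plus1_cell_sd = 15,
                         read_jitter_sd = 0)
  coh <- simulate_cohort(sc)
  dens <- reads_to_density(coh$reads, 147, c(chrSim = coh$chrom_length))
  fl <- find_flanking(coh$genes, coh$calls)
  pp <- align_average(dens, data.frame(chrom = fl$chrom, strand = fl$strand,
                                       anchor = fl$plus1), 2000, "plus1")
  cfg <- fit_config(n_starts = 40, seed = 7)
  f_plain <- fit_profile(pp, cfg, basin = "direct")
  f_conv <- fit_convolved(pp, cfg)
  # the richer model fits at least as well, and recovers the true spacing;
  # the unconvolved estimate carries a small upward smearing bias, so the
  # two estimates agree only loosely
  expect_lte(f_conv$chi2, f_plain$chi2)
  expect_lt(abs(f_conv$dbar - 177), 3)
  expect_lt(abs(f_conv$dbar - f_plain$dbar), 6)
})

test_that("simultaneous fits prefer the generating scenario pair", {
  # both sides generated from one direct model
  plus <- noiseless_profile(A = 2, x0 = 0, dbar = 177)
  minus <- noiseless_minus_profile(A = 2, x0 = 0, dbar = 177)
  cfg <- fit_config(n_starts = 25, seed = 8)
  fits <- lapply(c("A", "B", "C", "D"), function(pr)
    simultaneous_fit(plus, minus, pr, cfg))
  chi2 <- vapply(fits, `[[`, numeric(1), "chi2")
  expect_equal(which.min(chi2), 1L)    # A = both direct
  expect_lt(fits[[1]]$chi2, 1e-16)
  expect_equal(fits[[1]]$dbar, 177, tolerance = 1e-5)
})

test_that("flat profiles are flagged unidentifiable, not fitted", {
  flat <- model_profile(seq(-200, 2000), rep(0.5, 2201))
  cfg <- fit_config(n_starts = 15, seed = 9)
  f <- fit_profile(flat, cfg, basin = "free")
  expect_false(f$converged)
})

test_that("fits are reproducible for a fixed restart seed", {
  prof <- noiseless_profile(A = 3, x0 = -10, dbar = 185)
  cfg <- fit_config(n_starts = 10, seed = 11)
  f1 <- fit_profile(prof, cfg, basin = "direct")
  f2 <- fit_profile(prof, cfg, basin = "direct")
  expect_identical(f1, f2)
})

test_that("spacing recovery is unbiased over replicate cohorts", {
  # jitter-free cohorts isolate the fitting machinery from the known
  # convolution bias of jittered reads
  errs <- vapply(1:12, function(i) {
    sc <- synthetic_config(seed = 300 + i, n_genes = 300, read_jitter_sd = 0,
                           multimap_fraction = 0)
    coh <- simulate_cohort(sc)
    dens <- reads_to_density(coh$reads, 147, c(chrSim = coh$chrom_length))
    fl <- find_flanking(coh$genes, coh$calls)
    pp <- align_average(dens, data.frame(chrom = fl$chrom, strand = fl$strand,
                                         anchor = fl$plus1), 2000, "plus1")
    f <- fit_profile(pp, fit_config(n_starts = 20, seed = i), basin = "direct")
    f$dbar - 177
  }, numeric(1))
  expect_lt(abs(mean(errs)), 1)
})

test_that("uniform density gives a genic/intergenic ratio of one", {
  tracks <- list(chrSim = rep(0.25, 50000))
  dm <- statpos:::new_density_map(tracks)
  genes <- data.frame(feature_id = c("a", "b"), chrom = "chrSim",
                      strand = "+", tss = c(10000, 30000),
                      orf_end = c(15000, 36000), stringsAsFactors = FALSE)
  calls <- data.frame(chrom = "chrSim", dyad = c(9900, 10050, 29900, 30050),
                      fuzziness = 5, stringsAsFactors = FALSE)
  r <- density_ratio(dm, genes, calls)
  expect_equal(r$ratio, 1)
  # NFR base pairs (strictly between the flanking dyads) leave both partitions
  expect_equal(r$genic_bp + r$intergenic_bp + 2 * 149, 50000)
})
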