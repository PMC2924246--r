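p177 <- tonks_params(147, 177)

test_that("canonical sampler: packing limit, feasibility, non-overlap", {
  set.seed(1)
  cfg <- sample_tonks(L = 10 * 147, N = 10, b = 147)
  lefts <- cfg$midpoints - 147 / 2
  expect_equal(lefts, (0:9) * 147, tolerance = 1e-9)  # zero free length
  expect_error(sample_tonks(L = 1000, N = 10, b = 147), "infeasible")
  for (i in 1:20) {
    cf <- sample_tonks(L = 177 * 50, N = 50, b = 147)
    expect_true(all(diff(cf$midpoints) >= 147))
  }
})

test_that("canonical bulk gaps follow the exponential linker law", {
  set.seed(2)
  cfg <- sample_tonks(L = 177 * 2000, N = 2000, b = 147)
  gaps <- diff(cfg$midpoints) - 147
  n <- length(gaps)
  expect_lt(abs(mean(gaps) - 30), 3 * 30 / sqrt(n))
  # variance of Exp(30) is 900; canonical correction at N=2000 is ~0.1%
  expect_lt(abs(var(gaps) - 900), 3 * 900 * sqrt(2 / n) + 30)
})

test_that("half-line gas reproduces the Erlang positions of the k-th rod", {
  set.seed(3)
  n_rep <- 4000
  first_pinned <- replicate(n_rep, sample_gas_halfline(800, p177, "pinned")[1])
  # k = 1 from a pinned rod: b + Exp(ell)
  expect_lt(abs(mean(first_pinned) - 177), 3 * 30 / sqrt(n_rep))
  first_wall <- replicate(n_rep, sample_gas_halfline(800, p177, "wall")[1])
  # first rod against a wall: contact + Exp(ell)
  expect_lt(abs(mean(first_wall) - 30), 3 * 30 / sqrt(n_rep))
})

test_that("pinned-origin Monte Carlo histogram matches the analytic density", {
  set.seed(4)
  mc <- mc_barrier_density(20000, p177, x_max = 1000, bin = 5)
  ana <- ana_bin_means(seq(0, 995, 5), 5, p177)
  chk <- mc_agrees(mc, ana)
  expect_true(chk$ok)
})

test_that("read generation: round trip, multimap weight conservation,
           Poisson totals", {
  sc0 <- synthetic_config(seed = 9, read_jitter_sd = 0, multimap_fraction = 0)
  set.seed(9)
  cfg <- sample_tonks(L = 177 * 500, N = 500, b = 147)
  reads <- generate_reads(cfg, sc0)
  # Poisson sum over 500 nucleosomes at mean 6
  expect_lt(abs(nrow(reads) - 3000), 3 * sqrt(3000))
  dm <- reads_to_density(reads, 147)
  tr <- dm$tracks[[1]]
  dyads <- round(cfg$midpoints)
  # with zero jitter the density lives exactly on the true dyads, with
  # per-dyad weight equal to that nucleosome's read count
  expect_true(all(which(tr > 0) - 1 %in% dyads))
  mids <- reads$start + 73
  expect_true(all(mids %in% dyads))
  cnt <- table(mids)
  expect_equal(unname(tr[as.integer(names(cnt)) + 1]), as.vector(cnt))
  # multimap: total weight = number of distinct read identifiers
  sc1 <- synthetic_config(seed = 10, read_jitter_sd = 0,
                          multimap_fraction = 0.1, multimap_copies = 5)
  set.seed(10)
  reads_mm <- generate_reads(cfg, sc1)
  dm_mm <- reads_to_density(reads_mm, 147)
  expect_equal(dm_mm$total_weight, length(unique(reads_mm$read_id)))
})

test_that("cohort generation is deterministic and keeps its bookkeeping", {
  sc <- synthetic_config(seed = 21, n_genes = 40)
  a <- simulate_cohort(sc)
  b <- simulate_cohort(sc)
  expect_identical(a$reads, b$reads)
  expect_identical(a$calls, b$calls)
  expect_identical(a$genes, b$genes)
  expect_identical(a$truth, b$truth)
  # every call is one of the truth anchors
  expect_true(all(a$calls$dyad %in% c(a$truth$p1_call, a$truth$m1_call)))
})

test_that("found flanking nucleosomes equal the generator truth", {
  sc <- synthetic_config(seed = 22, n_genes = 150, read_jitter_sd = 0)
  coh <- simulate_cohort(sc)
  fl <- find_flanking(coh$genes, coh$calls)
  s <- ifelse(coh$truth$strand == "+", 1, -1)
  # the +1 rule presumes the +1 call is at or downstream of the TSS; the
  # generator's Gaussian TSS offset makes rare upstream exceptions
  regular <- s * (coh$truth$p1_call - coh$truth$tss) >= 0
  expect_gt(mean(regular), 0.95)
  expect_equal(fl$plus1[regular], coh$truth$p1_call[regular])
  expect_equal(fl$minus1[regular], coh$truth$m1_call[regular])
})

test_that("cohort gap distribution matches the configured NFR law", {
  sc <- synthetic_config(seed = 23, n_genes = 400)
  coh <- simulate_cohort(sc)
  pd <- position_distributions(coh$genes, coh$calls, b = 147)
  g <- pd$distances$gap[!is.na(pd$distances$gap)]
  # indirect -1 anchors sit ~ell/cells closer to the NFR than the wall target
  bias_allow <- 2 * 30 / sc$cells_per_gene
  expect_lt(abs(mean(g) - sc$gap_mean),
            3 * sd(g) / sqrt(length(g)) + bias_allow)
})

test_that("empty cohort yields empty, well-formed tables", {
  sc <- synthetic_config(seed = 1, n_genes = 0)
  coh <- simulate_cohort(sc)
  expect_equal(nrow(coh$reads), 0)
  expect_equal(nrow(coh$genes), 0)
  expect_named(coh$reads, c("chrom", "start", "end", "read_id", "score",
                            "strand"))
})
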