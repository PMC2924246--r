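mk_genes <- function(tss, strand = "+", orf_end = tss + 1500,
                     chrom = "chrSim") {
  data.frame(feature_id = sprintf("g%02d", seq_along(tss)), chrom = chrom,
             strand = strand, tss = tss, orf_end = orf_end,
             stringsAsFactors = FALSE)
}
mk_calls <- function(dyads, chrom = "chrSim")
  data.frame(chrom = chrom, dyad = dyads, fuzziness = 5,
             stringsAsFactors = FALSE)

test_that("flanking nucleosomes: at-or-downstream rule and strand mirror", {
  g <- mk_genes(1000)
  fl <- find_flanking(g, mk_calls(c(900, 1000, 1200)))
  expect_equal(fl$plus1, 1000)      # equality counts as downstream
  expect_equal(fl$minus1, 900)
  gc_ <- mk_genes(5000, strand = "-", orf_end = 3500)
  flc <- find_flanking(gc_, mk_calls(c(4800, 5100)))
  expect_equal(flc$plus1, 4800)     # downstream = decreasing coordinate
  expect_equal(flc$minus1, 5100)
  # absence is NA, not an error
  fl0 <- find_flanking(mk_genes(100), mk_calls(c(500, 700)))
  expect_true(is.na(fl0$minus1))
  expect_equal(fl0$plus1, 500)
})

test_that("3' end anchors swap the inclusive side", {
  g <- mk_genes(1000, orf_end = 3000)
  fl3 <- find_flanking(g, mk_calls(c(2800, 3000, 3200)), anchor = "three_prime")
  expect_equal(fl3$minus1, 3000)    # at-or-upstream of the ORF end
  expect_equal(fl3$plus1, 3200)
  gc_ <- mk_genes(5000, strand = "-", orf_end = 2000)
  fl3c <- find_flanking(gc_, mk_calls(c(1800, 2000, 2300)),
                        anchor = "three_prime")
  expect_equal(fl3c$minus1, 2000)
  expect_equal(fl3c$plus1, 1800)
})

test_that("alignment is anchored, oriented and averaged per gene", {
  tracks <- list(chrSim = numeric(10000))
  tracks$chrSim[3001] <- 1          # weight 1 at coordinate 3000
  dm <- statpos:::new_density_map(tracks)
  a1 <- data.frame(chrom = "chrSim", strand = "+", anchor = 3000)
  pr <- align_average(dm, a1, window = 500)
  expect_equal(pr$mean_weight[pr$offset == 0], 1)
  expect_equal(sum(pr$mean_weight), 1)
  # opposite strands: spikes 100 bp downstream in transcription direction
  tracks2 <- list(chrSim = numeric(10000))
  tracks2[["chrSim"]][c(3101, 6901)] <- 1    # 3000+100 (+), 7000-100 (-)
  dm2 <- statpos:::new_density_map(tracks2)
  a2 <- data.frame(chrom = "chrSim", strand = c("+", "-"),
                   anchor = c(3000, 7000))
  pr2 <- align_average(dm2, a2, window = 500)
  expect_equal(pr2$mean_weight[pr2$offset == 100], 1)
  expect_equal(pr2$mean_weight[pr2$offset == -100], 0)
  # linearity: profile of a sum is the sum of profiles
  dm_sum <- statpos:::new_density_map(list(chrSim = tracks$chrSim +
                                             tracks2$chrSim))
  pr_sum <- align_average(dm_sum, a2, window = 500)
  pra <- align_average(dm, a2, window = 500)
  expect_equal(pr_sum$mean_weight, pra$mean_weight + pr2$mean_weight)
  # offsets beyond the chromosome leave the denominator
  a_edge <- data.frame(chrom = "chrSim", strand = "+", anchor = 100)
  pr_e <- align_average(dm, a_edge, window = 500)
  expect_equal(pr_e$n_genes[pr_e$offset < -100], rep(0L, 400))
  expect_error(align_average(dm, a1[0, ], window = 500), "no anchors")
})

test_that("mirroring the profile flips offsets and preserves values", {
  prof <- model_profile(-5:5, 1:11)
  m <- mirror_profile(prof)
  expect_equal(m$offset, -5:5)
  expect_equal(m$mean_weight, 11:1)
  expect_true(attr(m, "mirrored"))
})

test_that("gap arithmetic and distance distributions", {
  g <- mk_genes(400)
  fl_gap <- position_distributions(g, mk_calls(c(353, 553)), b = 147)
  expect_equal(fl_gap$distances$gap, 53)        # (553 - 353) - 147 + 0.. = 53
  touching <- position_distributions(g, mk_calls(c(353, 500)), b = 147)
  expect_equal(touching$distances$gap, 0)
  expect_equal(sum(fl_gap$gap$prob), 1)
})

test_that("gene subsets follow the strict length and isolation rules", {
  g <- mk_genes(c(1000, 10000, 20000), orf_end = c(3000, 12000, 20500))
  g$orf_end[1] <- 3000    # length 2000 exactly: excluded by strict >
  long <- subset_genes(g, "long2000")
  expect_false("g01" %in% long$feature_id)
  expect_false("g03" %in% long$feature_id)
  # isolated gene kept; a neighbour end 600 bp upstream discards
  g2 <- rbind(mk_genes(10000),
              mk_genes(8500, orf_end = 9400))   # ends 600 bp upstream of g1
  g2$feature_id <- c("a", "b")
  clean <- subset_genes(g2, "clean_upstream1000")
  expect_false("a" %in% clean$feature_id)
  expect_true("b" %in% clean$feature_id)
  g3 <- rbind(mk_genes(10000), mk_genes(8000, orf_end = 8400))
  g3$feature_id <- c("a", "b")
  clean3 <- subset_genes(g3, "clean_upstream1000")
  expect_true("a" %in% clean3$feature_id)       # nearest feature 1600 bp away
  expect_error(subset_genes(g, "nope"))
  # subset sizes agree with an independent brute scan on a synthetic cohort
  sc <- synthetic_config(seed = 31, n_genes = 120)
  coh <- simulate_cohort(sc)
  long_n <- sum(abs(coh$genes$orf_end - coh$genes$tss) > 2000)
  expect_equal(nrow(subset_genes(coh$genes, "long2000")), long_n)
  expect_equal(long_n / 120, 1 / 3, tolerance = 0.45)  # heavy length tail
})
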