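#!/usr/bin/env Rscript

# Step 1 -- generate the synthetic promoter cohort.
#
# Emulates the inputs of the nucleosome-positioning analysis: strand-
# resolved mononucleosome reads, the -1/+1 nucleosome calls flanking each
# promoter NFR, and the gene table. The cohort is asymmetric by
# construction: the +1 nucleosome is directly positioned (pinned), the -1
# nucleosome statistically positioned against the repelling NFR edge --
# the boundary-condition pair the downstream analysis should rediscover.

suppressPackageStartupMessages(library(statpos))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

sc <- synthetic_config(seed = seed, n_genes = 800L)
cat(sprintf("simulating %d genes (dbar = %g bp, ~%g reads/nucleosome, seed %d)\n",
            sc$n_genes, sc$dbar, sc$reads_per_nucleosome_mean, seed))
coh <- run_simulate(sc, "results/data")
cat(sprintf("wrote results/data: %d reads, %d calls, %d genes\n",
            nrow(coh$reads), nrow(coh$calls), nrow(coh$genes)))
cat(sprintf("gene lengths: median %d bp, %.0f%% above 2000 bp\n",
            round(median(abs(coh$genes$orf_end - coh$genes$tss))),
            100 * mean(abs(coh$genes$orf_end - coh$genes$tss) > 2000)))
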