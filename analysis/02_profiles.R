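#!/usr/bin/env Rscript

# Step 2 -- density map and metagene alignment.
#
# Builds the read-midpoint density map (reciprocal multi-mapping weights),
# finds each gene's -1/+1 nucleosomes, aligns the density to those anchors
# with transcription oriented left to right, and writes the averaged
# profiles plus the position/gap distributions.

suppressPackageStartupMessages(library(statpos))

reads <- read_reads("results/data/reads.bed")
calls <- read_calls("results/data/calls.tsv")
genes <- read_genes("results/data/genes.tsv")
sizes <- read_chrom_sizes("results/data/chrom.sizes")

dens <- reads_to_density(reads, b = 147, chrom_sizes = sizes)
cat(sprintf("density map: %.0f read weight over %d bp\n",
            dens$total_weight, sum(lengths(dens$tracks))))

fl <- find_flanking(genes, calls)
cat(sprintf("anchors: %d/+1 and %d/-1 genes with flanking calls\n",
            sum(!is.na(fl$plus1)), sum(!is.na(fl$minus1))))

dir.create("results/profiles", recursive = TRUE, showWarnings = FALSE)
pp <- align_average(dens, data.frame(chrom = fl$chrom, strand = fl$strand,
                                     anchor = fl$plus1), 2000, "plus1")
pm <- align_average(dens, data.frame(chrom = fl$chrom, strand = fl$strand,
                                     anchor = fl$minus1), 2000, "minus1")
write_tsv(as.data.frame(pp), "results/profiles/profile_plus1.tsv")
write_tsv(as.data.frame(pm), "results/profiles/profile_minus1.tsv")

pd <- position_distributions(genes, calls, b = 147)
write_tsv(pd$plus1_tss, "results/profiles/plus1_tss_distribution.tsv")
write_tsv(pd$minus1_tss, "results/profiles/minus1_tss_distribution.tsv")
write_tsv(pd$gap, "results/profiles/gap_distribution.tsv")
ok <- !is.na(pd$distances$plus1_tss)
cat(sprintf("+1 sits %.0f bp downstream of the TSS on average; gap mean %.0f bp\n",
            mean(pd$distances$plus1_tss[ok]),
            mean(pd$distances$gap, na.rm = TRUE)))

# long-gene subset profile for the robustness comparison
long <- subset_genes(genes, "long2000")
fl_l <- fl[fl$feature_id %in% long$feature_id, ]
pl <- align_average(dens, data.frame(chrom = fl_l$chrom, strand = fl_l$strand,
                                     anchor = fl_l$plus1), 2000, "plus1")
write_tsv(as.data.frame(pl), "results/profiles/profile_plus1_long2000.tsv")
cat(sprintf("long-gene subset: %d genes\n", nrow(long)))
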