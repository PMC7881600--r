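#!/usr/bin/env Rscript

# Step 1 -- build the synthetic dataset that stands in for the sequenced
# animal: a segment library for the chromosome 17 safe-harbor locus and the
# SRY-GFP donor, ground-truth alleles (26 bp NHEJ insertion; ~38 kb
# seven-copy concatemer with one backbone copy; 18 kb three-copy
# derivative at one tenth abundance), PacBio-like long reads at ~50X per
# allele and 150 bp paired-end short reads at 100X.

suppressPackageStartupMessages(library(kiresolve))

cfg <- default_config(seed = 1L)
sim <- run_simulate(cfg, outdir = "results/simulation")

cat("Alleles simulated:\n")
print(sim$manifest$alleles)
cat(sprintf("\nLong reads: %d (%.1f Mb; mean %.0f bp)\n",
            nrow(sim$long$reads), sum(nchar(sim$long$reads$seq)) / 1e6,
            mean(nchar(sim$long$reads$seq))))
cat(sprintf("Short-read pairs: %d\n", nrow(sim$short$truth)))
cat("Outputs under results/simulation/ (FASTQ, FASTA, truth tables).\n")
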