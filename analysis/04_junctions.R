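#!/usr/bin/env Rscript

# Step 4 -- junction discovery from short reads: the terminal 50 nt of each
# plasmid/template edge become 26 overlapping 25-mers; reads containing any
# of them (or their reverse complement) are selected, error-trimmed by
# within-set k-mer abundance, assembled by greedy maximal-overlap extension,
# and the contigs annotated against the references. Expected calls include
# the homology-repair outer boundaries (no gRNA footprint), 20 bp partial
# gRNA-site footprints, and the 56 bp / 9 bp backbone fragments.

suppressPackageStartupMessages(library(kiresolve))

cfg <- default_config(seed = 1L)
sim <- run_simulate(cfg)
lib <- sim$lib
refs <- c(puc = segment_seq(lib, "PUC"),
          template = build_complete_template(lib)$seq)
idx <- build_edge_index(refs, cfg$edge_len, cfg$edge_k)
reads <- read_set(c(sim$short$r1$id, sim$short$r2$id),
                  c(sim$short$r1$seq, sim$short$r2$seq))
sel <- select_reads(reads, idx)
trimmed <- error_trim(sel$reads, cfg$trim_cutoff, cfg$edge_k)
contigs <- assemble_greedy(trimmed, cfg$asm_min_overlap, cfg$edge_k)
wt <- build_allele(lib, sim$blueprints$wildtype)$seq
calls <- annotate_contigs(contigs, c(refs, chr17 = wt), lib$grna_site)

dir.create("results", showWarnings = FALSE)
write.table(data.frame(edge = names(sel$per_edge), n_reads = sel$per_edge),
            "results/edge_selected_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_fasta(contigs, "results/junction_contigs.fasta")
write.table(calls, "results/junction_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Selected %d reads; %d survived trimming; %d contigs; %d junction calls.\n",
            nrow(sel$reads), nrow(trimmed), nrow(contigs), nrow(calls)))
print(table(calls$annotation))
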